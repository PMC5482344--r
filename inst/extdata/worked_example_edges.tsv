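# Determined (active/inactive) pairs of the 8-drug x 4-target worked
# example; the six unreported pairs are unknown-by-omission.
drug	target	status
d1	t1	active
d1	t2	active
d1	t4	active
d2	t2	active
d2	t3	active
d2	t4	inactive
d3	t1	active
d3	t4	inactive
d4	t1	active
d4	t2	active
d4	t3	active
d4	t4	inactive
d5	t1	inactive
d5	t2	active
d5	t4	active
d6	t1	active
d6	t2	inactive
d6	t3	inactive
d6	t4	active
d7	t1	active
d7	t2	active
d7	t3	active
d7	t4	active
d8	t2	inactive
d8	t3	active
d8	t4	active
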