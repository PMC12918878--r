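sample	day	replicate	batch	condition
d0_a	0	a	batch1	LB_10day
d0_b	0	b	batch1	LB_10day
d0_c	0	c	batch1	LB_10day
d1_a	1	a	batch2	LB_10day
d1_b	1	b	batch2	LB_10day
d1_c	1	c	batch2	LB_10day
d4_a	4	a	batch3	LB_10day
d4_b	4	b	batch3	LB_10day
d4_c	4	c	batch3	LB_10day
d10_a	10	a	batch4	LB_10day
d10_b	10	b	batch4	LB_10day
d10_c	10	c	batch4	LB_10day
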