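fate	dpERK	Mirr	Pnt	Rho	Aos	Br	description
F1	0	0	0	0	0	0	undifferentiated / main-body follicle cell
F2	0	0	0	0	0	1	roof: persistent Br, EGF activity quenched
F3	1	0	0	0	0	0	posterior domain, low EGF activity (Mid blocks Mirr)
F4	1	0	0	0	0	1	posterior domain, low EGF activity with persistent Br
F5	1	1	0	0	0	1	roof with ongoing low EGF activity (Br and Mirr)
F6	1	1	0	1	0	0	anterior band: Mirr and low Rho, Br repressed by Dpp
F7	2	0	1	0	0	0	posterior domain, high EGF activity (Mid blocks Mirr and Aos)
F8	2	1	1	2	1	0	operculum and floor: full EGF response (high dpERK, Rho, Aos, Pnt)
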