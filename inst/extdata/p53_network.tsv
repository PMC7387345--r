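#! species
name	role	init	scalable
DNAdam	damage-lesion	0	FALSE
ATMi	protein	10000	TRUE
ATMa	protein	0	TRUE
p53	protein	25212	TRUE
p53A	protein	0	TRUE
p53K	protein	0	TRUE
Mdm2m	mRNA	55	FALSE
Mdm2c	protein	1693	TRUE
Mdm2n	protein	3866	TRUE
Mdm2nI	protein-complex	0	TRUE
Wip1m	mRNA	4	FALSE
Wip1	protein	455	TRUE
PTENm	mRNA	22	FALSE
PTEN	protein	6127	TRUE
PIP2	protein	28520	TRUE
PIP3	protein	11480	TRUE
AKT	protein	485	TRUE
AKTp	protein	9515	TRUE
p21m	mRNA	15	FALSE
p21	protein	980	TRUE
ProC	protein	10000	TRUE
Casp	protein	0	TRUE
Gm_off	DNA-state	1.726	FALSE
Gm_on	DNA-state	0.274	FALSE
Gw_off	DNA-state	1.994	FALSE
Gw_on	DNA-state	0.006	FALSE
Gp_off	DNA-state	1.853	FALSE
Gp_on	DNA-state	0.147	FALSE
G21_off	DNA-state	1.853	FALSE
G21_on	DNA-state	0.147	FALSE
INHd	drug-pool	0	FALSE
INHb	drug-pool	0	FALSE
#! reactions
id	k	fac	rate	hill	reactants	products	pk
repair	v_rep	1		DNAdam:K_rep:1	DNAdam:1		FALSE
atm_act	k_atm	1		DNAdam:K_dam:2;ATMi:Km_atm:1	ATMi:1	ATMa:1	FALSE
atm_deact	kd_atm	1	ATMa:1		ATMa:1	ATMi:1	FALSE
atm_wip1	kw_atm	1	Wip1:1	ATMa:Km_atm:1	ATMa:1	ATMi:1	FALSE
p53_syn	s_p53	1				p53:1	FALSE
p53_deg	d_p53	1	p53:1		p53:1		FALSE
p53a_deg	d_p53	1	p53A:1		p53A:1		FALSE
p53k_deg	d_p53	1	p53K:1		p53K:1		FALSE
p53_mdm2	g_mdm	1	p53:1,Mdm2n:1		p53:1		FALSE
p53a_mdm2	g_mdm	1	p53A:1,Mdm2n:1		p53A:1		FALSE
p53k_mdm2	g_mdm_k	1	p53K:1,Mdm2n:1		p53K:1		FALSE
p53_phos	k_ph1	1	ATMa:1	p53:Km_p53:1	p53:1	p53A:1	FALSE
p53a_deph	k_deph1	1	p53A:1		p53A:1	p53:1	FALSE
p53a_wip1	k_wip_a	1	Wip1:1	p53A:Km_p53:1	p53A:1	p53:1	FALSE
p53a_phos2	k_ph2	1	ATMa:1	p53A:Km_p53:1	p53A:1	p53K:1	FALSE
p53k_deph	k_deph2	1	p53K:1		p53K:1	p53A:1	FALSE
p53k_wip1	k_wip_k	1	Wip1:1	p53K:Km_p53:1	p53K:1	p53A:1	FALSE
gm_on0	q0_mdm2	1	Gm_off:1		Gm_off:1	Gm_on:1	FALSE
gm_on1	q1_mdm2	1	Gm_off:1,p53A:1		Gm_off:1	Gm_on:1	FALSE
gm_off	q_off	1	Gm_on:1		Gm_on:1	Gm_off:1	FALSE
mdm2_tx	s_mdm2	1	Gm_on:1			Mdm2m:1	FALSE
mdm2m_deg	d_mdm2m	1	Mdm2m:1		Mdm2m:1		FALSE
mdm2_tl	t_mdm2	1	Mdm2m:1			Mdm2c:1	FALSE
mdm2c_deg	d_mdm2c	1	Mdm2c:1		Mdm2c:1		FALSE
mdm2_imp	k_imp	1	Mdm2c:1,AKTp:1		Mdm2c:1	Mdm2n:1	FALSE
mdm2n_deg	d_mdm2n	1	Mdm2n:1		Mdm2n:1		FALSE
inh_bind	ka_inh	1	Mdm2n:1,INHb:1		Mdm2n:1	Mdm2nI:1	FALSE
inh_unbind	kd_inh	1	Mdm2nI:1		Mdm2nI:1	Mdm2n:1	FALSE
mdm2nI_deg	d_mdm2n	1	Mdm2nI:1		Mdm2nI:1		FALSE
gw_on0	q0_wip1	1	Gw_off:1		Gw_off:1	Gw_on:1	FALSE
gw_on1	q1_wip1	1	Gw_off:1,p53A:2		Gw_off:1	Gw_on:1	FALSE
gw_off	q_off	1	Gw_on:1		Gw_on:1	Gw_off:1	FALSE
wip1_tx	s_1	0.5	Gw_on:1			Wip1m:1	FALSE
wip1m_deg	d_wip1m	1	Wip1m:1		Wip1m:1		FALSE
wip1_tl	t_wip1	1	Wip1m:1			Wip1:1	FALSE
wip1_deg	d_wip1	1	Wip1:1		Wip1:1		FALSE
gp_on0	q0_pten	1	Gp_off:1		Gp_off:1	Gp_on:1	FALSE
gp_on1	q1_pten	1	Gp_off:1,p53K:2		Gp_off:1	Gp_on:1	FALSE
gp_off	q_off	1	Gp_on:1		Gp_on:1	Gp_off:1	FALSE
pten_tx	s_2	0.5	Gp_on:1			PTENm:1	FALSE
ptenm_deg	d_ptenm	1	PTENm:1		PTENm:1		FALSE
pten_tl	t_pten	1	PTENm:1			PTEN:1	FALSE
pten_deg	d_pten	1	PTEN:1		PTEN:1		FALSE
pip_phos	k_pi3k	1	PIP2:1		PIP2:1	PIP3:1	FALSE
pip_deph	k_pten	1	PIP3:1,PTEN:1		PIP3:1	PIP2:1	FALSE
pip_deph0	k_pip_b	1	PIP3:1		PIP3:1	PIP2:1	FALSE
akt_phos	k_akt	1	PIP3:1	AKT:Km_akt:1	AKT:1	AKTp:1	FALSE
akt_deph	k_dakt	1		AKTp:Km_akt:1	AKTp:1	AKT:1	FALSE
g21_on0	q0_p21	1	G21_off:1		G21_off:1	G21_on:1	FALSE
g21_on1	q1_p21	1	G21_off:1,p53A:1		G21_off:1	G21_on:1	FALSE
g21_off	q_off	1	G21_on:1		G21_on:1	G21_off:1	FALSE
p21_tx	s_p21	1	G21_on:1			p21m:1	FALSE
p21m_deg	d_p21m	1	p21m:1		p21m:1		FALSE
p21_tl	t_p21	1	p21m:1			p21:1	FALSE
p21_deg	d_p21	1	p21:1		p21:1		FALSE
proc_syn	s_casp	1				ProC:1	FALSE
proc_deg	d_casp0	1	ProC:1		ProC:1		FALSE
casp_act	k_c1	1	ProC:1	p53K:K_kill:4	ProC:1	Casp:1	FALSE
casp_fb	k_c2	1	ProC:1	Casp:K_cfb:2	ProC:1	Casp:1	FALSE
casp_deg	d_casp	1	Casp:1		Casp:1		FALSE
pk_lib	d_r1	1	INHd:1		INHd:1	INHb:1	TRUE
pk_elim	d_r2	1	INHb:1		INHb:1		TRUE
pk_drip	q_drip	1				INHb:1	TRUE
#! parameters
name	value
k_dsb	3.5000000000000000e+01
v_rep	5.5000000000000003e-04
K_rep	5.0000000000000000e+00
k_atm	1.6000000000000000e+01
K_dam	1.4000000000000000e+01
Km_atm	1.2000000000000000e+02
kd_atm	1.0000000000000000e-04
kw_atm	6.7000000000000002e-04
s_p53	1.0000000000000000e+01
d_p53	1.0000000000000001e-05
g_mdm	9.9999999999999995e-08
g_mdm_k	3.4999999999999998e-07
Km_p53	3.8000000000000000e+03
k_ph1	1.1999999999999999e-03
k_deph1	1.0000000000000000e-04
k_wip_a	6.4999999999999997e-04
k_ph2	4.0000000000000001e-03
k_deph2	5.0000000000000002e-05
k_wip_k	1.3999999999999999e-04
q_off	6.3000000000000003e-04
q0_mdm2	1.0000000000000000e-04
q1_mdm2	9.9999999999999995e-08
q0_wip1	1.9999999999999999e-06
q1_wip1	2.5999999999999998e-10
q0_pten	5.0000000000000002e-05
q1_pten	5.6000000000000000e-11
q0_p21	5.0000000000000002e-05
q1_p21	2.9999999999999999e-07
s_mdm2	2.0000000000000000e-02
d_mdm2m	1.0000000000000000e-04
t_mdm2	2.9999999999999999e-02
d_mdm2c	4.0000000000000002e-04
k_imp	5.9999999999999995e-08
d_mdm2n	2.5000000000000001e-04
ka_inh	1.0000000000000000e-03
kd_inh	1.0000000000000000e-03
s_1	1.0000000000000001e-01
d_wip1m	8.0000000000000007e-05
t_wip1	2.3000000000000000e-02
d_wip1	2.0000000000000001e-04
s_2	2.9999999999999999e-02
d_ptenm	1.0000000000000000e-04
t_pten	5.0000000000000001e-03
d_pten	1.8000000000000000e-05
k_pi3k	2.9999999999999997e-04
k_pten	1.1999999999999999e-07
k_pip_b	1.0000000000000001e-05
k_akt	4.2000000000000002e-04
k_dakt	2.5000000000000000e+00
Km_akt	5.0000000000000000e+02
s_p21	2.0000000000000000e-02
d_p21m	2.0000000000000001e-04
t_p21	2.0000000000000000e-02
d_p21	2.9999999999999997e-04
s_casp	5.0000000000000000e-01
d_casp0	5.0000000000000002e-05
k_c1	2.0000000000000001e-04
K_kill	4.0600000000000000e+04
k_c2	1.0000000000000000e-03
K_cfb	4.0000000000000000e+03
d_casp	1.0000000000000000e-04
casp_thresh	5.0000000000000000e+03
d_r1	2.7777777777777778e-04
d_r2	6.9444444444444444e-05
q_drip	0.0000000000000000e+00
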