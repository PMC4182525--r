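# Simplified element+context atom typing for the all-atom score terms, v1.
# lj_radius/lj_welldepth: Lennard-Jones r_min contribution (A) and well depth
# (kcal/mol); lk_*: Lazaridis-Karplus solvation parameters (dGfree kcal/mol,
# correlation length A, atomic volume A^3); charge in elementary charges;
# donor/acceptor: hydrogen-bond capability of the heavy atom.
type	lj_radius	lj_welldepth	lk_dgfree	lk_lambda	lk_volume	charge	donor	acceptor
CH	2.00	0.12	0.60	3.5	14.7	0.00	0	0
CAbb	2.00	0.12	0.40	3.5	14.7	0.07	0	0
CObb	2.00	0.12	0.20	3.5	14.7	0.51	0	0
Nbb	1.75	0.17	-5.00	3.5	11.2	-0.47	1	0
Npol	1.75	0.17	-4.50	3.5	11.2	-0.45	1	1
OCbb	1.55	0.16	-5.85	3.5	10.8	-0.51	0	1
Oacc	1.55	0.16	-5.30	3.5	10.8	-0.55	0	1
OHx	1.55	0.16	-6.70	3.5	10.8	-0.66	1	1
OOC	1.55	0.16	-10.00	3.5	10.8	-0.76	0	1
Phos	2.15	0.20	-4.00	3.5	14.7	1.50	0	0
S	2.00	0.45	-3.20	3.5	17.0	-0.10	0	0
H	1.00	0.05	0.00	3.5	0.0	0.15	0	0
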