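sample	arm	sex	subgroup	deep_wgs	cnv_call_failed	small_cnv_qc_failed	phenotypes
P79	case	female	cns_plus_other	0	0	0	ntd
P102	case	female	cns_plus_other	0	0	0	ntd
P240	case	female	cns_plus_other	0	0	0	ntd
P103	case	female	cns_plus_other	0	0	0	ntd
P350	case	female	cns_plus_other	0	0	0	ntd
P482	case	female	cns_plus_other	0	0	0	ntd
P155	case	female	cns_plus_other	0	0	0	ntd
P351	case	female	cns_plus_other	0	0	0	ntd
P438	case	female	cns_plus_other	0	0	0	ntd
P871	case	female	cns_plus_other	0	0	0	ntd
P747	case	female	cns_plus_other	0	0	0	ntd
P901	case	female	cns_plus_other	0	0	0	ntd
P827	case	female	cns_plus_other	0	0	0	ntd
P1008	case	female	cns_plus_other	0	0	0	ntd
P1142	case	female	cns_plus_other	0	0	0	ntd
P1506	case	female	cns_plus_other	0	0	0	ntd
P112	case	female	cns_plus_other	0	0	0	ntd
P772	case	female	cns_only	0	0	0	ntd
P938	case	female	cns_plus_other	0	0	0	ntd
P864	case	female	cns_plus_other	0	0	0	ntd
P470	case	female	cns_only	0	0	0	ntd
P244	case	female	cns_plus_other	0	0	0	ntd
P186	case	female	cns_plus_other	0	0	0	ntd
P116	case	female	cns_only	0	0	0	ntd
P456	case	female	cns_only	1	0	0	ntd
P190	case	female	cns_only	0	0	0	ntd
P238	case	female	cns_only	0	0	0	ntd
P422	case	female	cns_only	1	0	0	ntd
P653	case	female	cns_only	1	0	0	hydrocephalus
P532	case	female	cns_only	1	0	0	ventriculomegaly
P664	case	female	cns_only	1	0	0	acc
P931	case	female	cns_only	1	0	0	holoprosencephaly
P796	case	female	cns_only	1	0	0	cerebellar_hypoplasia
P882	case	female	cns_plus_other	1	0	0	cerebellar_hypoplasia
P884	case	female	cns_only	1	0	0	ventriculomegaly
P954	case	female	cns_only	1	0	0	ventriculomegaly
P810	case	female	cns_only	1	0	0	dandy_walker
P1004	case	female	cns_only	1	0	0	microcephaly
P49	case	female	cns_plus_other	1	0	0	arachnoid_cyst
P432	case	female	cns_only	1	0	0	microcephaly
P211	case	female	cns_only	1	0	0	microcephaly
P234	case	female	cns_plus_other	1	0	0	destructive_lesion
P246	case	female	cns_only	1	0	0	cerebellar_hypoplasia
P273	case	female	cns_plus_other	1	0	0	abnormal_echo
P348	case	female	cns_plus_other	1	0	0	hydrocephalus
P357	case	female	cns_plus_other	1	0	0	ventriculomegaly
P431	case	female	cns_only	1	0	0	cerebellar_hypoplasia
P464	case	female	cns_plus_other	1	0	0	acc
P479	case	female	cns_only	1	0	0	holoprosencephaly
P558	case	female	cns_plus_other	1	0	0	holoprosencephaly
P627	case	female	cns_plus_other	1	0	0	cerebellar_hypoplasia
P648	case	female	cns_only	1	0	0	dandy_walker
P730	case	female	cns_plus_other	1	0	0	microcephaly
P733	case	female	cns_only	1	0	0	holoprosencephaly
P836	case	female	cns_only	1	0	0	holoprosencephaly
P903	case	female	cns_plus_other	1	0	0	arachnoid_cyst
P924	case	female	cns_only	1	0	0	cerebellar_hypoplasia
P2942	case	female	cns_only	1	0	0	dandy_walker
P993	case	female	cns_only	1	0	0	destructive_lesion
P1278	case	female	cns_plus_other	1	0	0	ntd
P222	case	female	cns_plus_other	1	0	0	abnormal_echo
P114	case	female	cns_only	1	0	0	hydrocephalus
P1133	case	male	cns_plus_other	1	0	0	chiari_ii
P135	case	female	cns_only	1	0	0	ntd
P382	case	female	cns_only	1	0	0	ntd
P175	case	female	cns_only	1	0	0	ntd
P866	case	female	cns_only	1	0	0	ntd
P37	case	female	cns_plus_other	1	0	0	ntd;microcephaly
P221	case	female	cns_only	1	0	0	hydrocephalus
S001	case	female	cns_plus_other	1	0	0	ventriculomegaly
S002	case	female	cns_plus_other	1	0	0	acc
S003	case	female	cns_plus_other	1	0	0	holoprosencephaly
S004	case	female	cns_plus_other	1	0	0	cerebellar_hypoplasia
S005	case	female	cns_plus_other	1	0	0	dandy_walker
S006	case	female	cns_plus_other	1	0	0	microcephaly
S007	case	female	cns_plus_other	1	0	0	arachnoid_cyst
S008	case	female	cns_plus_other	1	0	0	destructive_lesion
S009	case	female	cns_plus_other	1	0	0	abnormal_echo
S010	case	female	cns_plus_other	1	0	0	hydrocephalus
S011	case	female	cns_plus_other	1	0	0	ventriculomegaly
S012	case	female	cns_plus_other	1	0	0	acc
S013	case	female	cns_only	1	0	0	holoprosencephaly
S014	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S015	case	male	cns_only	1	0	0	dandy_walker
S016	case	male	cns_only	1	0	0	microcephaly
S017	case	male	cns_only	1	0	0	arachnoid_cyst
S018	case	male	cns_only	1	0	0	destructive_lesion
S019	case	male	cns_only	1	0	0	abnormal_echo
S020	case	male	cns_only	1	0	0	hydrocephalus
S021	case	male	cns_only	1	0	0	ventriculomegaly
S022	case	male	cns_only	1	0	0	acc
S023	case	male	cns_only	1	0	0	holoprosencephaly
S024	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S025	case	male	cns_only	1	0	0	dandy_walker
S026	case	male	cns_only	1	0	0	microcephaly
S027	case	male	cns_only	1	0	0	arachnoid_cyst
S028	case	male	cns_only	1	0	0	destructive_lesion
S029	case	male	cns_only	1	0	0	abnormal_echo
S030	case	male	cns_only	1	0	0	hydrocephalus
S031	case	male	cns_only	1	0	0	ventriculomegaly
S032	case	male	cns_only	1	0	0	acc
S033	case	male	cns_only	1	0	0	holoprosencephaly
S034	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S035	case	male	cns_only	1	0	0	dandy_walker
S036	case	male	cns_only	1	0	0	microcephaly
S037	case	male	cns_only	1	0	0	arachnoid_cyst
S038	case	male	cns_only	1	0	0	destructive_lesion
S039	case	male	cns_only	1	0	0	abnormal_echo
S040	case	male	cns_only	1	0	0	hydrocephalus
S041	case	male	cns_only	1	0	0	ventriculomegaly
S042	case	male	cns_only	1	0	0	acc
S043	case	male	cns_only	1	0	0	holoprosencephaly
S044	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S045	case	male	cns_only	1	0	0	dandy_walker
S046	case	male	cns_only	1	0	0	microcephaly
S047	case	male	cns_only	1	0	0	arachnoid_cyst
S048	case	male	cns_only	1	0	0	destructive_lesion
S049	case	male	cns_only	1	0	0	abnormal_echo
S050	case	male	cns_only	1	0	0	hydrocephalus
S051	case	male	cns_only	1	0	0	ventriculomegaly
S052	case	male	cns_only	1	0	0	acc
S053	case	male	cns_only	1	0	0	holoprosencephaly
S054	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S055	case	male	cns_only	1	0	0	dandy_walker
S056	case	male	cns_only	1	0	0	microcephaly
S057	case	male	cns_only	1	0	0	arachnoid_cyst
S058	case	male	cns_only	1	0	0	destructive_lesion
S059	case	male	cns_only	1	0	0	abnormal_echo
S060	case	male	cns_only	1	0	0	hydrocephalus
S061	case	male	cns_only	1	0	0	ventriculomegaly
S062	case	male	cns_only	1	0	0	acc
S063	case	male	cns_only	1	0	0	holoprosencephaly
S064	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S065	case	male	cns_only	1	0	0	dandy_walker
S066	case	male	cns_only	1	0	0	microcephaly
S067	case	male	cns_only	1	0	0	arachnoid_cyst
S068	case	male	cns_only	1	0	0	destructive_lesion
S069	case	male	cns_only	1	0	0	abnormal_echo
S070	case	male	cns_only	1	0	0	hydrocephalus
S071	case	male	cns_only	1	0	0	ventriculomegaly
S072	case	male	cns_only	1	0	0	acc
S073	case	male	cns_only	1	0	0	holoprosencephaly
S074	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S075	case	male	cns_only	1	0	0	dandy_walker
S076	case	male	cns_only	1	0	0	microcephaly
S077	case	male	cns_only	1	0	0	arachnoid_cyst
S078	case	male	cns_only	1	0	0	destructive_lesion
S079	case	male	cns_only	1	0	0	abnormal_echo
S080	case	male	cns_only	1	0	0	hydrocephalus
S081	case	male	cns_only	1	0	0	ventriculomegaly
S082	case	male	cns_only	1	0	0	acc
S083	case	male	cns_only	1	0	0	holoprosencephaly
S084	case	male	cns_only	1	0	0	cerebellar_hypoplasia
S085	case	male	cns_only	1	0	0	dandy_walker
S086	case	male	cns_only	1	0	1	microcephaly
S087	case	male	cns_only	1	0	1	arachnoid_cyst
S088	case	male	cns_only	1	0	1	destructive_lesion
S089	case	male	cns_only	1	0	1	abnormal_echo
S090	case	male	cns_only	1	1	0	hydrocephalus
S091	case	male	cns_only	1	1	0	ventriculomegaly
S092	case	male	cns_only	1	1	0	acc
S093	case	male	cns_only	1	0	0	holoprosencephaly
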