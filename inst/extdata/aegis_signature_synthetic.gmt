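JUN	synthetic_regulon	SYNT001	SYNT002	SYNT003	SYNT004	SYNT005	SYNT006	SYNT007	SYNT008	SYNT009	SYNT010	SYNT011	SYNT012	SYNT013	SYNT014	SYNT015	SYNT016	SYNT017	SYNT018	SYNT019	SYNT020	SYNT021	SYNT022	SYNT023	SYNT024	SYNT025	SYNT026	SYNT027	SYNT028	SYNT029	SYNT030	SYNT031	SYNT032	SYNT033	SYNT034	SYNT035	SYNT036	SYNT037	SYNT038	SYNT039	SYNT040	SYNT041	SYNT042	SYNT043	SYNT044	SYNT045	SYNT046	SYNT047	SYNT104	SYNT119	SYNT143	SYNT182	SYNT191	SYNT204
ATF3	synthetic_regulon	SYNT040	SYNT048	SYNT049	SYNT050	SYNT051	SYNT052	SYNT053	SYNT054	SYNT055	SYNT056	SYNT057	SYNT058	SYNT059	SYNT060	SYNT061	SYNT062	SYNT063	SYNT064	SYNT065	SYNT066	SYNT067	SYNT068	SYNT069	SYNT070	SYNT071	SYNT072	SYNT073	SYNT074	SYNT075	SYNT076	SYNT077	SYNT078	SYNT079	SYNT080	SYNT081	SYNT082	SYNT083	SYNT155	SYNT183	SYNT218
FOXO3	synthetic_regulon	SYNT031	SYNT053	SYNT055	SYNT084	SYNT085	SYNT086	SYNT087	SYNT088	SYNT089	SYNT090	SYNT091	SYNT092	SYNT093	SYNT094	SYNT095	SYNT096	SYNT097	SYNT098	SYNT099	SYNT100	SYNT101	SYNT102	SYNT103	SYNT104	SYNT105	SYNT106	SYNT107	SYNT108	SYNT109	SYNT110	SYNT111	SYNT112	SYNT113	SYNT114	SYNT115	SYNT116	SYNT117	SYNT146
E2F3	synthetic_regulon	SYNT023	SYNT118	SYNT119	SYNT120	SYNT121	SYNT122	SYNT123	SYNT124	SYNT125	SYNT126	SYNT127	SYNT128	SYNT129	SYNT130	SYNT131	SYNT132	SYNT133	SYNT134	SYNT135	SYNT136	SYNT137	SYNT138	SYNT139	SYNT140	SYNT141	SYNT142	SYNT143	SYNT144	SYNT145	SYNT146	SYNT147	SYNT148	SYNT163	SYNT176	SYNT216
PPARG	synthetic_regulon	SYNT001	SYNT149	SYNT150	SYNT151	SYNT152	SYNT153	SYNT154	SYNT155	SYNT156	SYNT157	SYNT158	SYNT159	SYNT160	SYNT161	SYNT162	SYNT163	SYNT164	SYNT165	SYNT166	SYNT167	SYNT168	SYNT169	SYNT170	SYNT171	SYNT172	SYNT173	SYNT174	SYNT175	SYNT220	SYNT238
REST	synthetic_regulon	SYNT086	SYNT089	SYNT176	SYNT177	SYNT178	SYNT179	SYNT180	SYNT181	SYNT182	SYNT183	SYNT184	SYNT185	SYNT186	SYNT187	SYNT188	SYNT189	SYNT190	SYNT191	SYNT192	SYNT193	SYNT194	SYNT195	SYNT196	SYNT197	SYNT198	SYNT199	SYNT200	SYNT240
FOXA1	synthetic_regulon	SYNT036	SYNT055	SYNT092	SYNT201	SYNT202	SYNT203	SYNT204	SYNT205	SYNT206	SYNT207	SYNT208	SYNT209	SYNT210	SYNT211	SYNT212	SYNT213	SYNT214	SYNT215	SYNT216	SYNT217	SYNT218	SYNT219	SYNT220	SYNT221	SYNT222
TFAP4	synthetic_regulon	SYNT010	SYNT142	SYNT195	SYNT223	SYNT224	SYNT225	SYNT226	SYNT227	SYNT228	SYNT229	SYNT230	SYNT231	SYNT232	SYNT233	SYNT234	SYNT235	SYNT236	SYNT237	SYNT238	SYNT239	SYNT240	SYNT241
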