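ingredient_id	name	herbs	caco2	dl	literature_flag	concentration	conc_unit	method
COM1	4',5,6,7-Tetrahydroxyflavanone 6,7-di-O-b-D-glucopyranoside		—	—	TRUE	—		HPLC-ESI-MS
COM2	5-Hydroxymethylfurfural		—	—	TRUE	10.38	ug/ml	UHPLC
COM3	6-Hydroxykaemferol 3,6,7-tri-O-b-D-glucopyranoside		—	—	TRUE	—		HPLC-ESI-MS
COM4	6-Hydroxykaemferol 3,6-di-O-b-Dglucopyranosyl-7-O-b-Dglucuronopyranoside		—	—	TRUE	—		HPLC-ESI-MS
COM5	Anhydrosafflor yellow B		—	—	TRUE	—		HPLC-ESI-MS
COM6	Benzoylpaeoniflorin		—	—	TRUE	39.82	ug/ml	UHPLC
COM7	Butylidenephthalide		—	—	TRUE	0.02	ug/ml	UHPLC
COM8	Catechinic acid		—	—	TRUE	5.76	ug/ml	UHPLC
COM9	Chlorogenic Acid		—	—	TRUE	3.92	ug/ml	UHPLC
COM10	Ethyl ferulate		—	—	TRUE	0.19	ug/ml	UHPLC
COM11	Gallic acid		—	—	TRUE	6.60	ug/ml	UHPLC
COM12	Galuteolin		—	—	TRUE	1.10	ug/ml	UHPLC
COM13	Hydroxysafflor yellow A		—	—	TRUE	479.45	ug/ml	UHPLC
COM14	Hyperoside		—	—	TRUE	0.63	ug/ml	UHPLC
COM15	Naringenin		—	—	TRUE	0.35	ug/ml	UHPLC
COM16	Protocatechuic aldehyde		—	—	TRUE	7.28	mg/L	HPLC
COM17	Rosmarinic acid		—	—	TRUE	5.07	ug/ml	UHPLC
COM18	Safflor yellow A		—	—	TRUE	48.79	mg/L	HPLC
COM19	Senkyunolide H		—	—	TRUE	19.48	mg/L	HPLC
COM20	Senkyunolide I		—	—	TRUE	53.89	mg/L	HPLC
COM21	Sodium Danshensu		—	—	TRUE	0.49	ug/ml	UHPLC
COM22	Tanshinone IIA		—	—	TRUE	0.10	ug/ml	UHPLC
COM23	Uridine		—	—	TRUE	38.61	mg/L	HPLC
MOL000105	Protocatechuic acid		—	—	TRUE	4.81	ug/ml	UHPLC
MOL000223	Caffeic acid		—	—	TRUE	5.25	ug/ml	UHPLC
MOL000389	Ferulic acid		—	—	TRUE	35.12	ug/ml	UHPLC
MOL000415	Rutin		—	—	TRUE	2.27	ug/ml	UHPLC
MOL000874	Paeonol		—	—	TRUE	0.03	ug/ml	UHPLC
MOL001924	Paeoniflorin		—	—	TRUE	1963.86	mg/L	HPLC
MOL001932	Galloylpaeoniflorin		—	—	TRUE	—		HPLC-ESI-MS
MOL002687	Guanosine		—	—	TRUE	27.15	mg/L	HPLC
MOL007004	Albiflorin		—	—	TRUE	26.24	ug/ml	UHPLC
MOL007006	Oxypaeoniflorin		—	—	TRUE	40.54	ug/ml	UHPLC
MOL007074	Salvianolic acid B		—	—	TRUE	2.14	ug/ml	UHPLC
MOL007134	Danshensu		—	—	TRUE	48.49	mg/L	HPLC
MOL007136	Salvianolic acid A		—	—	TRUE	0.04	ug/ml	UHPLC
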