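!Series_title	"Synthetic stand-in for a germination/outgrowth expression time course (generated, not measured)"
!Series_summary	"Noiseless logistic profiles for loader tests; values are log2 intensities."
!Sample_geo_accession	"GSM90001"	"GSM90002"	"GSM90003"	"GSM90004"	"GSM90005"	"GSM90006"	"GSM90007"	"GSM90008"	"GSM90009"	"GSM90010"	"GSM90011"	"GSM90012"	"GSM90013"	"GSM90014"
!Sample_title	"T0min"	"T5min"	"T10min"	"T15min"	"T20min"	"T25min"	"T30min"	"T40min"	"T50min"	"T60min"	"T70min"	"T80min"	"T90min"	"T100min"
!series_matrix_table_begin
"ID_REF"	"GSM90001"	"GSM90002"	"GSM90003"	"GSM90004"	"GSM90005"	"GSM90006"	"GSM90007"	"GSM90008"	"GSM90009"	"GSM90010"	"GSM90011"	"GSM90012"	"GSM90013"	"GSM90014"
"BSU04730_sigB_at"	7.357852	7.489218	7.732279	8.138750	8.733790	9.490070	10.337838	11.965732	13.018921	13.425977	13.535551	13.561211	13.567001	13.568296
"BSU04720_rsbW_at"	7.357852	7.489218	7.732279	8.138750	8.733790	9.490070	10.337838	11.965732	13.018921	13.425977	13.535551	13.561211	13.567001	13.568296
"BSU04710_rsbV_at"	7.357852	7.489218	7.732279	8.138750	8.733790	9.490070	10.337838	11.965732	13.018921	13.425977	13.535551	13.561211	13.567001	13.568296
"BSU40410_rsbU_at"	7.663130	7.684307	7.727963	7.815511	7.982126	8.271834	8.711852	9.873273	10.783089	11.155259	11.256888	11.280767	11.286159	11.287366
"BSU29410_rsbP_at"	6.658962	6.675609	6.710092	6.779893	6.915038	7.156673	7.537719	8.602659	9.474235	9.836343	9.935637	9.958990	9.964265	9.965445
"BSU25200_sigA_at"	9.648068	9.652747	9.662562	9.682949	9.724437	9.805505	9.952303	10.493498	11.075718	11.349448	11.427337	11.445822	11.450005	11.450942
"BSU16170_dnaK_at"	8.969155	8.972901	8.980768	8.997143	9.030605	9.096520	9.217593	9.680924	10.203567	10.455996	10.528476	10.545717	10.549622	10.550496
!series_matrix_table_end
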