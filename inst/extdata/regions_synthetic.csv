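"id","acronym","name","parent","anatomical_group","volume"
"1","R001","Region R001",NA,"Div01",2.75393444024592
"2","R002","Region R002",NA,"Div01",0.0236796119981685
"3","R003","Region R003",NA,"Div02",4.66647683089695
"4","R004","Region R004",NA,"Div02",3.5894603777143
"5","R005","Region R005",NA,"Div03",0.0166915434207017
"6","R006","Region R006",NA,"Div03",0.244254279638285
"7","R007","Region R007",NA,"Div04",0.11301795723767
"8","R008","Region R008",NA,"Div04",2.78330017629962
"9","R009","Region R009",NA,"Div05",0.160826503116643
"10","R010","Region R010",NA,"Div05",1.80447313732757
"11","R011","Region R011",NA,"Div06",0.978922808917611
"12","R012","Region R012",NA,"Div06",1.54530246776466
"13","R013","Region R013",NA,"Div07",0.111555917836107
"14","R014","Region R014",NA,"Div07",0.706728405985879
"15","R015","Region R015",NA,"Div08",0.0102484089715418
"16","R016","Region R016",NA,"Div08",1.77017220295682
"17","R017","Region R017",NA,"Div09",0.0104663352695369
"18","R018","Region R018",NA,"Div09",0.0363467294917851
"19","R019","Region R019",NA,"Div10",2.79827250688292
"20","R020","Region R020",NA,"Div10",0.447890868215574
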