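"Cruise","Station","Occupation","Event","Depth (m)","Parameter","Fraction","Concentration","SD","Syphoned volume (l)","Notes"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"BSI","t0",0.466614,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"BSI","top",0.3,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"BSI","base",1.23948,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"BSI","tray",4.83398,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"POC","t0",16.6646,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"POC","top",10,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"POC","base",47.5791,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d01",60,"POC","tray",191.359,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"BSI","t0",0.36248,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"BSI","top",0.3,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"BSI","base",0.652304,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"BSI","tray",2.00024,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"POC","t0",14.5018,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"POC","top",10,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"POC","base",35.3839,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d02",160,"POC","tray",132.504,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"BSI","t0",0.324992,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"BSI","top",0.3,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"BSI","base",0.440922,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"BSI","tray",0.980097,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"POC","t0",13.1204,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"POC","top",10,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"POC","base",27.5947,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d03",400,"POC","tray",94.9133,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"BSI","t0",0.314281,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"BSI","top",0.3,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"BSI","base",0.380527,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"BSI","tray",0.688627,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"POC","t0",12.4946,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"POC","top",10,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"POC","base",24.0659,0,,"synthetic fixture"
"SYNS","ST001","O1","SYNS_ST001_d04",700,"POC","tray",77.8829,0,,"synthetic fixture"
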