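"Cruise","Station","Event","Depth (m)","Parameter","Slow flux","Fast flux","Total flux"
"SYNS","ST001","SYNS_ST001_d01",60,"BSI",1.5,3.5,5
"SYNS","ST001","SYNS_ST001_d01",60,"POC",60,140,200
"SYNS","ST001","SYNS_ST001_d02",160,"BSI",0.5625,1.3125,1.875
"SYNS","ST001","SYNS_ST001_d02",160,"POC",40.5288,94.5672,135.096
"SYNS","ST001","SYNS_ST001_d03",400,"BSI",0.225,0.525,0.75
"SYNS","ST001","SYNS_ST001_d03",400,"POC",28.0923,65.5488,93.6411
"SYNS","ST001","SYNS_ST001_d04",700,"BSI",0.128571,0.3,0.428571
"SYNS","ST001","SYNS_ST001_d04",700,"POC",22.4581,52.4022,74.8603
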