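hibernaculum_id,plot_id,species,occupancy,lost,E1,V1,E2,V2,E3,V3,V6,E4,V4,V5,V7,E5,E6
A001,A,reducta,full,FALSE,0,1,0,0,0,0,,1,0,,,0,0
A002,A,reducta,full,FALSE,1,0,1,0,0,0,,0,0,,,0,1
A003,A,reducta,full,FALSE,0,0,1,0,0,0,,0,0,,,1,0
A004,A,unknown,empty,TRUE,0,0,0,0,1,0,,1,0,,,0,1
A005,A,reducta,full,TRUE,0,0,1,0,0,0,,0,0,,,0,0
A006,A,camilla,full,FALSE,0,0,1,0,0,0,,0,0,,,0,0
A007,A,unknown,empty,FALSE,1,0,0,0,0,0,,0,0,,,0,0
A008,A,reducta,full,FALSE,1,0,0,0,1,0,,0,0,,,0,0
A009,A,unknown,empty,FALSE,1,0,1,1,0,1,,0,0,,,0,0
A010,A,reducta,full,FALSE,0,0,1,1,1,1,,1,0,,,1,0
A011,A,unknown,empty,FALSE,0,0,1,1,0,0,,1,0,,,0,0
A012,A,unknown,empty,FALSE,1,0,0,0,0,1,,0,0,,,0,0
A013,A,reducta,full,FALSE,1,0,1,0,0,0,,0,0,,,0,0
A014,A,reducta,full,FALSE,0,0,1,0,1,0,,0,0,,,0,1
A015,A,unknown,empty,FALSE,0,1,1,0,0,1,,0,0,,,1,0
A016,A,reducta,full,FALSE,1,0,0,0,1,0,,0,0,,,0,1
A017,A,reducta,full,FALSE,0,0,0,0,0,0,,0,0,,,1,0
A018,A,unknown,empty,FALSE,1,1,0,1,0,1,,0,0,,,0,1
A019,A,unknown,empty,FALSE,0,1,1,0,0,0,,0,1,,,0,1
A020,A,reducta,full,TRUE,0,0,1,0,0,0,,0,0,,,0,0
A021,A,reducta,full,FALSE,0,0,1,0,0,0,,0,0,,,0,0
A022,A,unknown,empty,FALSE,0,0,1,0,0,0,,0,0,,,0,0
A023,A,unknown,empty,FALSE,0,0,1,0,0,0,,1,0,,,0,1
A024,A,unknown,empty,FALSE,1,0,0,0,1,0,,1,0,,,0,0
A025,A,reducta,full,FALSE,0,1,0,1,1,1,,0,0,,,0,1
A026,A,unknown,empty,FALSE,1,1,0,0,0,0,,0,0,,,1,1
A028,A,unknown,empty,FALSE,1,0,1,0,1,1,,0,0,,,0,0
A029,A,reducta,full,FALSE,0,0,0,0,0,0,,1,1,,,0,0
A030,A,unknown,empty,FALSE,0,0,1,0,0,0,,0,0,,,0,1
A032,A,unknown,empty,FALSE,1,0,0,1,1,0,,1,0,,,0,0
B001,B,unknown,empty,FALSE,1,0,0,0,1,1,,0,,0,,1,
B002,B,reducta,full,FALSE,0,0,1,0,1,1,,1,,0,,0,
B004,B,unknown,empty,FALSE,1,0,0,1,0,0,,1,,0,,0,
B005,B,unknown,empty,FALSE,1,0,0,0,0,0,,0,,0,,0,
B006,B,unknown,empty,FALSE,1,0,1,0,0,0,,0,,0,,1,
B007,B,reducta,full,FALSE,0,0,1,0,0,0,,0,,0,,1,
B008,B,reducta,full,FALSE,1,0,0,0,0,0,,1,,0,,1,
B009,B,reducta,full,FALSE,0,0,0,0,0,0,,1,,0,,0,
B010,B,unknown,empty,FALSE,0,0,1,0,0,0,,1,,0,,0,
B012,B,unknown,empty,FALSE,1,0,0,0,0,0,,1,,0,,0,
B013,B,reducta,full,FALSE,0,0,0,0,1,0,,1,,0,,1,
B014,B,unknown,empty,FALSE,0,1,0,0,0,0,,0,,0,,0,
B015,B,reducta,full,FALSE,0,0,1,0,0,0,,0,,1,,0,
B016,B,unknown,empty,FALSE,0,0,1,0,1,0,,1,,0,,0,
B017,B,unknown,empty,FALSE,1,0,1,0,0,0,,0,,0,,0,
B018,B,reducta,full,FALSE,1,0,0,0,0,0,,0,,0,,0,
C001,C,unknown,empty,FALSE,1,0,1,0,0,,0,1,,,0,0,0
C002,C,reducta,full,FALSE,0,0,1,0,0,,0,1,,,0,0,0
C003,C,unknown,empty,FALSE,1,0,0,0,0,,0,0,,,0,0,0
C005,C,reducta,full,FALSE,1,0,0,0,1,,0,0,,,0,0,0
C006,C,reducta,full,FALSE,1,0,1,1,0,,0,0,,,0,0,0
C007,C,reducta,full,FALSE,1,1,0,1,1,,0,0,,,0,0,0
C008,C,reducta,full,FALSE,1,0,1,0,0,,0,1,,,0,0,0
C009,C,unknown,empty,FALSE,0,1,0,0,1,,0,0,,,0,0,0
C010,C,unknown,empty,FALSE,0,0,1,0,0,,0,0,,,0,0,0
C011,C,unknown,empty,FALSE,1,1,1,0,0,,0,0,,,0,0,1
C012,C,unknown,empty,FALSE,1,0,0,0,1,,1,0,,,1,0,0
C013,C,unknown,empty,FALSE,1,1,0,0,0,,0,0,,,0,0,0
C014,C,reducta,full,FALSE,0,0,0,0,1,,0,1,,,0,1,1
C015,C,reducta,full,FALSE,0,0,0,0,0,,0,0,,,0,1,0
C016,C,unknown,empty,FALSE,0,0,0,1,1,,0,1,,,0,0,1
C017,C,reducta,full,FALSE,0,0,1,0,0,,1,0,,,0,0,0
C018,C,reducta,full,FALSE,1,0,0,0,0,,0,0,,,0,0,0
C019,C,reducta,full,FALSE,1,0,0,0,1,,0,0,,,0,1,1
C020,C,reducta,full,FALSE,1,1,0,0,0,,0,0,,,0,0,0
C021,C,reducta,full,FALSE,0,0,1,0,1,,1,0,,,0,1,0
C022,C,reducta,full,FALSE,0,0,1,0,0,,0,0,,,1,0,0
C023,C,unknown,empty,FALSE,1,1,0,0,0,,0,0,,,0,0,0
C024,C,reducta,full,FALSE,0,0,1,0,0,,0,1,,,0,0,0
C025,C,unknown,empty,FALSE,0,0,0,0,0,,1,0,,,0,0,0
C026,C,reducta,full,FALSE,1,0,0,0,0,,0,0,,,1,0,0
C027,C,unknown,empty,FALSE,1,0,0,0,1,,0,0,,,1,0,0
C028,C,reducta,full,FALSE,0,0,1,0,0,,0,0,,,0,0,0
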