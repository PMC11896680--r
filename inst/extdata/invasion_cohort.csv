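case_id,surgeon,checklist_submitted,disease_status,diagnosis,reported_tnm,recommended,size_t,distant_mets,accuracy_override,items_not_reported
1,A,FALSE,primary,PDTC,pT3b N0 Mx,pT4a N0 Mx N-RLN^1 PE-Ph^1,,unknown,FALSE,"PNI, pharynx"
2,A,FALSE,primary,PDTC,pT1b N1a Mx,pT4a N1a Mx PE-E^0,,unknown,FALSE,Esophagus
3,A,FALSE,primary,PDTC,pT2 N1a Mx,pT3b N1a Mx M-SM,,unknown,FALSE,Muscle
4,A,FALSE,primary,PTC-FV,pT2 N1a Mx,pT4a N1a Mx N-RLN^1 PE-E^0 LT-T_3^0,,unknown,FALSE,"PNI, pharynx, esophagus, trachea"
5,A,FALSE,primary,PTC-FV,pT1a N1b Mx,pT4a N1b Mx N-RLN^1,,unknown,TRUE,RLN resection identified in operative report
6,A,FALSE,primary,PTC-TCV,pT2 N0 Mx,pT4a N0Mx M-SM/CT PE-E^0,,unknown,FALSE,"Muscle, esophagus"
7,A,FALSE,primary,PTC-FV,pT3a N0 Mx,pT3b N0 Mx M-SM,,unknown,FALSE,Muscle
8,A,FALSE,primary,PTC-TCV,pT3a N1a Mx,pT4a N1a Mx N-RLN^1 M-SM PE-E^0,,unknown,FALSE,"PNI, muscle, esophagus"
9,A,FALSE,primary,PTC,pT3a N1 Mx,pT3b N1 Mx M-SM,,unknown,FALSE,Muscle
10,A,FALSE,primary,PTC-TCV,pT3a N0a Mx,pT4a N0a Mx M-SM/CT PE-E^0 Ph^0,,unknown,FALSE,"Muscle, pharynx, esophagus"
11,A,FALSE,primary,PTC-TCV,pT2 N0a Mx,pT4a N0a Mx M-CT PE-E^0 Ph^0,,unknown,FALSE,"Pharynx, esophagus, muscle"
12,A,FALSE,primary,PTC-TCV,pT2 N1b Mx,pT3b N1b Mx M-SM/CT,,unknown,FALSE,Muscle
13,A,FALSE,primary,PTC-TCV,pT4a N1b Mx,R2 pT2 N1b Mx VAS-V_IJ/INN^1,T2,unknown,FALSE,Residual cervical gross disease at internal jugular vein & innominate vein
14,A,TRUE,primary,PTC-TCV,pT4a N1a M1,pT4a N1a M1 N-RLN^1 LT-T_2^0Cr^0 PE-E^0Ph^0,,present,FALSE,
15,A,TRUE,primary,PTC,pT3b N1a Mx,pT3b N1a M-SM,,unknown,FALSE,
16,A,TRUE,primary,PTC,pT4a N0 Mx,pT4a N0 Mx N-RLN^0,,unknown,FALSE,
17,A,TRUE,primary,PTC,pT4a N0 Mx,pT4a N0 Mx N-RLN^1 PE-Ph^0E^0,,unknown,FALSE,
18,A,TRUE,primary,Anaplastic,pT4a N1b M0,R1 pT4a N1b Mx N-RLN^1 PE-Ph^0 LT-T_1^0 M-SM,,unknown,FALSE,
19,A,TRUE,primary,PTC,PT3b N1a Mx,pT3b N1a Mx M-SM,,unknown,FALSE,
20,B,FALSE,primary,PTC-FV,pT1b N1a Mx,pT4a N1a Mx N-RLN^1,,unknown,FALSE,PNI
21,B,TRUE,primary,FC,pT4a N0 Mx,pT4a N0 Mx B-St^1 Clav^1,,unknown,FALSE,
22,B,TRUE,primary,PDTC,pT4a N1b Mx,pT4a N1b Mx N-RLN^1,,unknown,FALSE,
23,B,TRUE,primary,PTC-TCV,pT3b N1b Mx,pT3b N1b Mx M-SM,,unknown,FALSE,
24,B,TRUE,primary,PTC-TCF,pT4a N1b Mx,pT4a N1b Mx N-RLN^1,,unknown,FALSE,
25,B,TRUE,primary,PTC-TCV,pT4a N1b Mx,pT4a N1b Mx N-RLN^1 M-SCM,,unknown,FALSE,
26,B,TRUE,primary,PTC-TCV,pT4a N1b Mx,pT4a N1b Mx LT-T_1^0 N-RLN^1 PE-E^0,,unknown,FALSE,
27,B,TRUE,primary,PTC-TCV,pT4a N1a Mx,pT4a N1a Mx LT-T_2^0,,unknown,FALSE,
28,B,TRUE,primary,Medullary,PT4a N1b Mx,pT4a N1b Mx PE-E^0,,unknown,FALSE,
29,B,TRUE,primary,PTC-FV,pT4a N1a Mx,pT4a N1a Mx PE-E^0,,unknown,FALSE,
30,A,FALSE,recurrent,Recurrent PTC,,Rec N-RLN^0 M-SCM,,unknown,FALSE,"RLN, SCM"
31,B,FALSE,recurrent,Recurrent PTC-TCV,,Rec PE-E^0 N-RLN^1,,unknown,FALSE,"RLN, esophagus"
32,B,FALSE,recurrent,Recurrent PTC,,Rec PE-E^0 N-RLN^1 LT-CR^0,,unknown,FALSE,"Esophagus, RLN or cricoid"
33,B,FALSE,recurrent,Recurrent PTC,,Rec N-RLN^1,,unknown,FALSE,PNI
34,B,FALSE,recurrent,Recurrent PTC,,Rec N-Vag^1 VAS-Acc^1,,unknown,FALSE,PNI or carotid artery
35,B,FALSE,recurrent,Recurrent PTC,,Rec-LT-T^0_2,,unknown,FALSE,Trachea
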