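PedigreeID,ID,Sex,MotherID,FatherID,isProband,CurAge,isAff,Age,Geno
1,1,1,NA,NA,0,87,1,87,NA
1,2,0,NA,NA,0,69,0,NA,NA
1,3,1,NA,NA,0,85,0,NA,NA
1,4,0,NA,NA,0,82,1,74,NA
1,5,1,2,1,0,68,0,NA,NA
1,6,0,4,3,0,63,1,50,NA
1,7,0,6,5,1,51,0,NA,1
1,8,0,2,1,0,84,0,NA,NA
1,9,1,NA,NA,0,84,0,NA,NA
1,10,1,8,9,0,52,0,NA,NA
1,11,1,8,9,0,67,0,NA,NA
1,12,1,8,9,0,45,0,NA,NA
1,13,1,2,1,0,78,0,NA,NA
1,14,0,NA,NA,0,64,0,NA,NA
1,15,1,14,13,0,60,0,NA,NA
1,16,0,14,13,0,70,0,NA,NA
1,17,1,2,1,0,71,0,NA,NA
1,18,0,NA,NA,0,56,0,NA,NA
1,19,1,18,17,0,59,0,NA,NA
1,20,0,18,17,0,67,0,NA,NA
1,21,0,18,17,0,48,0,NA,NA
1,22,1,18,17,0,64,0,NA,NA
1,23,1,2,1,0,72,0,NA,NA
1,24,0,NA,NA,0,80,0,NA,NA
1,25,1,24,23,0,57,0,NA,NA
1,26,0,2,1,0,66,0,NA,NA
1,27,0,2,1,0,59,0,NA,NA
1,28,1,NA,NA,0,68,0,NA,NA
1,29,0,27,28,0,49,0,NA,NA
1,30,1,27,28,0,60,0,NA,NA
1,31,0,27,28,0,55,0,NA,NA
1,32,0,27,28,0,69,0,NA,NA
1,33,0,4,3,0,57,0,NA,NA
1,34,1,NA,NA,0,81,0,NA,NA
1,35,1,33,34,0,72,0,NA,NA
1,36,1,33,34,0,68,0,NA,NA
1,37,1,4,3,0,71,1,43,NA
1,38,0,6,5,0,69,1,48,NA
1,39,1,6,5,0,51,0,NA,NA
1,40,0,NA,NA,0,68,0,NA,NA
1,41,0,40,39,0,41,0,NA,NA
1,42,0,40,39,0,47,0,NA,NA
1,43,1,6,5,0,44,0,NA,NA
1,44,0,NA,NA,0,70,0,NA,NA
1,45,1,44,43,0,28,0,NA,NA
1,46,1,44,43,0,34,0,NA,NA
1,47,1,44,43,0,43,0,NA,NA
1,48,1,44,43,0,32,0,NA,NA
1,49,1,NA,NA,0,38,0,NA,NA
1,50,0,7,49,0,39,0,NA,NA
1,51,1,7,49,0,27,0,NA,NA
1,52,0,7,49,0,32,0,NA,NA
1,53,1,7,49,0,28,0,NA,NA
1,54,1,7,49,0,35,0,NA,NA
2,1,1,NA,NA,0,69,0,NA,NA
2,2,0,NA,NA,0,94,0,NA,NA
2,3,1,NA,NA,0,83,0,NA,NA
2,4,0,NA,NA,0,94,0,NA,NA
2,5,1,2,1,0,70,1,70,NA
2,6,0,4,3,0,76,0,NA,NA
2,7,1,6,5,1,66,0,NA,1
2,8,0,2,1,0,76,1,36,NA
2,9,1,NA,NA,0,71,0,NA,NA
2,10,0,8,9,0,51,0,NA,NA
2,11,1,2,1,0,68,1,38,NA
2,12,0,NA,NA,0,80,0,NA,NA
2,13,0,12,11,0,74,1,69,NA
2,14,0,2,1,0,68,0,NA,NA
2,15,1,4,3,0,72,0,NA,NA
2,16,0,NA,NA,0,71,0,NA,NA
2,17,0,16,15,0,53,1,37,NA
2,18,1,16,15,0,47,0,NA,NA
2,19,0,16,15,0,51,0,NA,NA
2,20,1,4,3,0,77,0,NA,NA
2,21,0,NA,NA,0,64,0,NA,NA
2,22,1,21,20,0,73,0,NA,NA
2,23,0,21,20,0,59,0,NA,NA
2,24,1,4,3,0,66,0,NA,NA
2,25,0,NA,NA,0,76,0,NA,NA
2,26,0,25,24,0,46,0,NA,NA
2,27,1,25,24,0,51,0,NA,NA
2,28,0,25,24,0,47,0,NA,NA
2,29,0,NA,NA,0,53,0,NA,NA
2,30,1,29,7,0,23,0,NA,NA
2,31,0,29,7,0,25,1,25,NA
2,32,0,29,7,0,18,0,NA,NA
3,1,1,NA,NA,0,70,0,NA,NA
3,2,0,NA,NA,0,90,0,NA,NA
3,3,1,NA,NA,0,86,1,86,NA
3,4,0,NA,NA,0,65,0,NA,NA
3,5,1,2,1,0,61,0,NA,NA
3,6,0,4,3,0,78,0,NA,NA
3,7,1,6,5,1,69,1,54,1
3,8,0,2,1,0,70,0,NA,NA
3,9,1,NA,NA,0,84,0,NA,NA
3,10,1,8,9,0,55,1,28,NA
3,11,0,8,9,0,68,0,NA,NA
3,12,0,2,1,0,73,0,NA,NA
3,13,1,4,3,0,56,0,NA,NA
3,14,0,NA,NA,0,60,0,NA,NA
3,15,0,14,13,0,78,0,NA,NA
3,16,0,14,13,0,56,0,NA,NA
3,17,0,4,3,0,51,0,NA,NA
3,18,1,NA,NA,0,73,0,NA,NA
3,19,0,17,18,0,57,0,NA,NA
3,20,1,4,3,0,70,0,NA,NA
3,21,0,NA,NA,0,60,0,NA,NA
3,22,1,21,20,0,55,0,NA,NA
3,23,1,4,3,0,84,0,NA,NA
3,24,0,NA,NA,0,70,0,NA,NA
3,25,0,24,23,0,45,0,NA,NA
3,26,0,24,23,0,47,0,NA,NA
3,27,0,6,5,0,58,0,NA,NA
3,28,1,NA,NA,0,52,0,NA,NA
3,29,1,27,28,0,36,0,NA,NA
3,30,0,27,28,0,43,0,NA,NA
3,31,1,6,5,0,49,0,NA,NA
3,32,0,NA,NA,0,69,0,NA,NA
3,33,1,32,31,0,23,0,NA,NA
3,34,1,32,31,0,31,0,NA,NA
3,35,0,32,31,0,39,0,NA,NA
3,36,0,NA,NA,0,61,0,NA,NA
3,37,0,36,7,0,29,0,NA,NA
3,38,1,36,7,0,33,0,NA,NA
3,39,0,36,7,0,32,0,NA,NA
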