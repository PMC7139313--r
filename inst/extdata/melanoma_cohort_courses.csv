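patient_no,tnm,course_index,agents,cycles,induction_cycles,tmr_im,tmr_days,tmr_day_secondary,tmr_lag,irae,irae_days,irae_im,irae_ambiguous,best_response,survival
1,"pT3a, N3c, M1a",1,ipilimumab,4,,IL-6,62,,FALSE,,,,FALSE,PR,>89
1,"pT3a, N3c, M1a",2,nivolumab,11,,,,,FALSE,thyroiditis,28,monocytes,FALSE,PR,>89
2,"pT1a, N3, M1c",1,ipilimumab,4,,IL-6,81,,FALSE,myositis;hepatitis,81;81,IL-6;CRP;monocytes,TRUE,PD,8.5
3,"pT4, N1b, M1c",1,ipilimumab,3,,,,,FALSE,thyroiditis,49,,FALSE,PD,19
4,"pT3a, N3, M1c",1,ipilimumab,4,,IL-6,16,,FALSE,hepatitis,77,monocytes;eosinophils,FALSE,PR,14
4,"pT3a, N3, M1c",2,nivolumab,7,,paradox,,,FALSE,,,,FALSE,PR,14
5,"pT3a, N3, M1c",1,ipilimumab,3,,IL-6,1,,FALSE,colitis,70,eosinophils,FALSE,PR,>6
5,"pT3a, N3, M1c",2,pembrolizumab,33,,IL-6,8;141,,FALSE,myositis,148,IL-6,FALSE,CR,>6
6,"pTx, N3, M1c",1,pembrolizumab,7,,paradox,,,FALSE,,,,FALSE,PD,8
7,"pT3b, N3, M1c",1,pembrolizumab,8,,IL-6;monocytes,5,,FALSE,pneumonitis,188,IL-6,FALSE,PR,>11
8,"pT2a, N2b, M1c",1,nivolumab,18,,,,,FALSE,,,,FALSE,PR,>51
8,"pT2a, N2b, M1c",2,nivolumab+ipilimumab,11,2,IL-6,40,,FALSE,hepatitis,40,IL-6;CRP,FALSE,CR,>51
9,"pT4a, N3, M0",1,pembrolizumab,9,,,,,FALSE,,,,FALSE,PD,8
10,"pT4a, N1a",1,pembrolizumab,19,,IL-6,71,,FALSE,,,,FALSE,PD,>13
11,"pTx, N0, M1c",1,pembrolizumab,28,,IL-6,141,21,FALSE,,,,FALSE,CR,>41
12,"pT3b, N1b, M1d",1,nivolumab+ipilimumab,1,,IL-6,6,,FALSE,neuritis,6,,FALSE,CR,27
13,"pT4, N1c, M0",1,nivolumab,3,,,,,FALSE,,,,FALSE,PD,14
14,"pTx, Nx, M1b",1,nivolumab+ipilimumab,1,,IL-6,28,,FALSE,thyroiditis;hepatitis,35;35,IL-6;CRP,FALSE,CR,>25
14,"pTx, Nx, M1b",2,nivolumab,7,,,,,FALSE,pneumonitis,182,IL-6;CRP;monocytes,FALSE,CR,>25
15,"pT2b, N3c, M1c",1,nivolumab+ipilimumab,2,,IL-6,7,112,TRUE,thyroiditis,21,IL-6;monocytes,FALSE,CR,>35
15,"pT2b, N3c, M1c",2,nivolumab,8,,IL-6,,,FALSE,myositis,98,IL-6,FALSE,CR,>35
16,"pTx, N2, M1a",1,nivolumab+ipilimumab,1,,IL-6,39,4,FALSE,rash;hypophysitis;pneumonitis,4;20;20,IL-6;monocytes,FALSE,CR,>11
17,"pT3a, N1b, M1c",1,nivolumab,1,,IL-6,28,,TRUE,vitiligo,70,eosinophils,FALSE,PR,>8
17,"pT3a, N1b, M1c",2,nivolumab+ipilimumab,10,4,CRP,,,FALSE,,,,FALSE,PR,>8
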