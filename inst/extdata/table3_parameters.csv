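patient_id,locomotion_type,parameter,side,manual,algorithm,rel_error_printed
1,wheelchair,stride_duration,Aff,2.09,1.72,17.70
1,wheelchair,stride_duration,NonAff,2.10,1.51,28.10
1,wheelchair,cadence,Aff,32.37,28.40,12.26
1,wheelchair,cadence,NonAff,28.78,31.80,-10.49
1,wheelchair,stride_count,Aff,9,8,11.11
1,wheelchair,stride_count,NonAff,8,9,-12.50
2,walker,stride_duration,Aff,1.17,1.14,2.56
2,walker,stride_duration,NonAff,1.18,1.13,4.24
2,walker,cadence,Aff,50.96,53.26,-4.51
2,walker,cadence,NonAff,51.46,53.41,-3.79
2,walker,stride_count,Aff,103,104,-0.97
2,walker,stride_count,NonAff,104,105,-0.96
3,wheelchair,stride_duration,Aff,1.24,1.23,0.81
3,wheelchair,stride_duration,NonAff,1.24,1.24,0.00
3,wheelchair,cadence,Aff,46.36,45.94,0.91
3,wheelchair,cadence,NonAff,46.36,46.20,0.35
3,wheelchair,stride_count,Aff,53,50,5.66
3,wheelchair,stride_count,NonAff,53,51,3.77
4,walker,stride_duration,Aff,1.06,1.07,-0.94
4,walker,stride_duration,NonAff,1.06,1.06,0.00
4,walker,cadence,Aff,56.76,56.42,0.60
4,walker,cadence,NonAff,56.76,56.82,-0.11
4,walker,stride_count,Aff,76,75,1.32
4,walker,stride_count,NonAff,76,76,0.00
5,walker,stride_duration,Aff,1.34,1.38,-2.99
5,walker,stride_duration,NonAff,1.34,1.36,-1.49
5,walker,cadence,Aff,45.21,44.23,2.17
5,walker,cadence,NonAff,44.73,44.46,0.60
5,walker,stride_count,Aff,93,88,5.38
5,walker,stride_count,NonAff,92,89,3.26
6,walker,stride_duration,Aff,1.30,1.28,1.54
6,walker,stride_duration,NonAff,1.27,1.23,3.15
6,walker,cadence,Aff,46.19,49.34,-6.82
6,walker,cadence,NonAff,47.37,49.76,-5.05
6,walker,stride_count,Aff,39,40,-2.56
6,walker,stride_count,NonAff,40,41,-2.50
7,wheelchair,stride_duration,Aff,1.92,1.91,0.52
7,wheelchair,stride_duration,NonAff,1.92,1.92,0.00
7,wheelchair,cadence,Aff,32.48,34.17,-5.20
7,wheelchair,cadence,NonAff,32.48,35.33,-8.77
7,wheelchair,stride_count,Aff,11,10,9.09
7,wheelchair,stride_count,NonAff,11,11,0.00
8,walker,stride_duration,Aff,1.14,1.07,6.14
8,walker,stride_duration,NonAff,1.14,1.07,6.14
8,walker,cadence,Aff,50.63,61.17,-20.82
8,walker,cadence,NonAff,51.71,61.38,-18.70
8,walker,stride_count,Aff,47,48,-2.13
8,walker,stride_count,NonAff,48,49,-2.08
9,walker,stride_duration,Aff,1.26,1.29,-2.38
9,walker,stride_duration,NonAff,1.27,1.29,-1.57
9,walker,cadence,Aff,47.60,47.75,-0.32
9,walker,cadence,NonAff,47.60,48.05,-0.95
9,walker,stride_count,Aff,86,83,3.49
9,walker,stride_count,NonAff,86,84,2.33
10,wheelchair,stride_duration,Aff,2.76,2.73,1.09
10,wheelchair,stride_duration,NonAff,2.73,2.68,1.83
10,wheelchair,cadence,Aff,21.96,22.80,-3.83
10,wheelchair,cadence,NonAff,21.96,23.89,-8.79
10,wheelchair,stride_count,Aff,10,9,10.00
10,wheelchair,stride_count,NonAff,10,10,0.00
11,walker,stride_duration,Aff,1.26,1.25,0.79
11,walker,stride_duration,NonAff,1.27,1.23,3.15
11,walker,cadence,Aff,47.12,49.40,-4.84
11,walker,cadence,NonAff,47.60,49.40,-3.78
11,walker,stride_count,Aff,98,98,0.00
11,walker,stride_count,NonAff,99,99,0.00
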