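study,design,baseline,treatment,estimate,variance
AB_01,AB,A,B,0.430871580995824,0.1
AB_02,AB,A,B,0.383070281647227,0.1
AB_03,AB,A,B,0.615614172512396,0.1
AC_01,AC,A,C,0.997903361077959,0.1
AC_02,AC,A,C,0.426614007610352,0.1
AC_03,AC,A,C,0.109463665790888,0.1
BC_01,BC,B,C,1.36826293697781,0.1
BC_02,BC,B,C,2.26405264774274,0.1
BC_03,BC,B,C,1.12522595834339,0.1
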