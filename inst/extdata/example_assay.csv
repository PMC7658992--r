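herbicide,duration,treatment,role,nominal_conc,replicate,cell_density_t0,cell_density_t72,fluorescence_F,fluorescence_Fm,measured_conc_start,measured_conc_end,ph_t0,ph_t72,salinity,dissolved_oxygen,temperature
synthetic_example,3,control,control,0,R1,3000,309443.858174078,264.130168562186,500,NA,NA,8.1,8.3,35,8.2,27
synthetic_example,3,control,control,0,R2,3000,320506.50432671,266.90605072187,500,NA,NA,8.1,8.3,35,8.2,27
synthetic_example,3,control,control,0,R3,3000,305156.867474936,270.563671573771,500,NA,NA,8.1,8.3,35,8.2,27
synthetic_example,3,control,control,0,R4,3000,316202.831517445,265.414858552436,500,NA,NA,8.1,8.3,35,8.2,27
synthetic_example,3,control,control,0,R5,3000,317424.098108032,271.116296823136,500,NA,NA,8.1,8.3,35,8.2,27
synthetic_example,3,T1,test,1,R1,3000,227219.299733486,318.062132643769,500,1.02537411432368,0.767889521899747,8.1,8.3,35,8.2,27
synthetic_example,3,T1,test,1,R2,3000,202386.430626033,322.442811912396,500,1.02537411432368,0.767889521899747,8.1,8.3,35,8.2,27
synthetic_example,3,T1,test,1,R3,3000,212589.841019373,328.605999211214,500,1.02537411432368,0.767889521899747,8.1,8.3,35,8.2,27
synthetic_example,3,T1,test,1,R4,3000,212958.604958232,319.173238462723,500,1.02537411432368,0.767889521899747,8.1,8.3,35,8.2,27
synthetic_example,3,T1,test,1,R5,3000,207441.967626546,314.811849612234,500,1.02537411432368,0.767889521899747,8.1,8.3,35,8.2,27
synthetic_example,3,T2,test,2.51188643150958,R1,3000,141895.96379222,357.662937471899,500,2.47538250823252,1.86543010069013,8.1,8.3,35,8.2,27
synthetic_example,3,T2,test,2.51188643150958,R2,3000,130182.270202842,355.678929291376,500,2.47538250823252,1.86543010069013,8.1,8.3,35,8.2,27
synthetic_example,3,T2,test,2.51188643150958,R3,3000,140330.989799252,358.757855312009,500,2.47538250823252,1.86543010069013,8.1,8.3,35,8.2,27
synthetic_example,3,T2,test,2.51188643150958,R4,3000,137079.04231218,355.114286542507,500,2.47538250823252,1.86543010069013,8.1,8.3,35,8.2,27
synthetic_example,3,T2,test,2.51188643150958,R5,3000,140331.951279017,370.519147746947,500,2.47538250823252,1.86543010069013,8.1,8.3,35,8.2,27
synthetic_example,3,T3,test,6.30957344480193,R1,3000,58315.6578558957,411.360112956754,500,6.68773445857773,4.86214635939709,8.1,8.3,35,8.2,27
synthetic_example,3,T3,test,6.30957344480193,R2,3000,60096.5634517512,426.747818713587,500,6.68773445857773,4.86214635939709,8.1,8.3,35,8.2,27
synthetic_example,3,T3,test,6.30957344480193,R3,3000,54180.252428378,417.44870576973,500,6.68773445857773,4.86214635939709,8.1,8.3,35,8.2,27
synthetic_example,3,T3,test,6.30957344480193,R4,3000,58973.344823319,420.678100203646,500,6.68773445857773,4.86214635939709,8.1,8.3,35,8.2,27
synthetic_example,3,T3,test,6.30957344480193,R5,3000,59053.5468129035,413.136540501718,500,6.68773445857773,4.86214635939709,8.1,8.3,35,8.2,27
synthetic_example,3,T4,test,15.8489319246111,R1,3000,20387.1815328169,463.031658066062,500,16.2856224812191,12.2243271052513,8.1,8.3,35,8.2,27
synthetic_example,3,T4,test,15.8489319246111,R2,3000,19436.9118964138,452.301856252353,500,16.2856224812191,12.2243271052513,8.1,8.3,35,8.2,27
synthetic_example,3,T4,test,15.8489319246111,R3,3000,19697.9291635891,461.303078317792,500,16.2856224812191,12.2243271052513,8.1,8.3,35,8.2,27
synthetic_example,3,T4,test,15.8489319246111,R4,3000,20399.9178928564,455.220240480048,500,16.2856224812191,12.2243271052513,8.1,8.3,35,8.2,27
synthetic_example,3,T4,test,15.8489319246111,R5,3000,21107.1561375611,450.398099230701,500,16.2856224812191,12.2243271052513,8.1,8.3,35,8.2,27
synthetic_example,3,T5,test,39.8107170553497,R1,3000,8110.9539453763,478.688734136646,500,42.1627530716375,31.1359888667358,8.1,8.3,35,8.2,27
synthetic_example,3,T5,test,39.8107170553497,R2,3000,7746.01916740947,484.061902223134,500,42.1627530716375,31.1359888667358,8.1,8.3,35,8.2,27
synthetic_example,3,T5,test,39.8107170553497,R3,3000,7988.15139980144,479.878398149409,500,42.1627530716375,31.1359888667358,8.1,8.3,35,8.2,27
synthetic_example,3,T5,test,39.8107170553497,R4,3000,8232.58385206901,480.911159335136,500,42.1627530716375,31.1359888667358,8.1,8.3,35,8.2,27
synthetic_example,3,T5,test,39.8107170553497,R5,3000,8335.31106244372,480.997027417336,500,42.1627530716375,31.1359888667358,8.1,8.3,35,8.2,27
synthetic_example,3,T6,test,100,R1,3000,4855.65255234761,498.717714210336,500,107.702144664974,86.636784648627,8.1,8.3,35,8.2,27
synthetic_example,3,T6,test,100,R2,3000,4622.48623137423,491.636288136179,500,107.702144664974,86.636784648627,8.1,8.3,35,8.2,27
synthetic_example,3,T6,test,100,R3,3000,4311.59241891683,492.582903992909,500,107.702144664974,86.636784648627,8.1,8.3,35,8.2,27
synthetic_example,3,T6,test,100,R4,3000,4448.44417003215,483.067245499453,500,107.702144664974,86.636784648627,8.1,8.3,35,8.2,27
synthetic_example,3,T6,test,100,R5,3000,4693.27420229556,486.769607026415,500,107.702144664974,86.636784648627,8.1,8.3,35,8.2,27
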