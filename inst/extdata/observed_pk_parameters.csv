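species,route,dose,dose_units,parameter,value,units
mouse,oral,5,mg/kg,cmax,132.0,ng/mL
mouse,oral,5,mg/kg,tmax,1.5,h
mouse,oral,5,mg/kg,t_half,18.37,h
mouse,oral,5,mg/kg,auc_0_t,497.1,ng.h/mL
mouse,oral,5,mg/kg,auc_0_inf,560.7,ng.h/mL
mouse,oral,5,mg/kg,cl_over_f_per_kg,8.92,L/h/kg
mouse,oral,5,mg/kg,mrt,9.60,h
mouse,oral,5,mg/kg,vss_over_f_per_kg,85.61,L/kg
mouse,oral,10,mg/kg,cmax,218.2,ng/mL
mouse,oral,10,mg/kg,tmax,2,h
mouse,oral,10,mg/kg,t_half,10.00,h
mouse,oral,10,mg/kg,auc_0_t,1063.0,ng.h/mL
mouse,oral,10,mg/kg,auc_0_inf,1107.7,ng.h/mL
mouse,oral,10,mg/kg,cl_over_f_per_kg,9.03,L/h/kg
mouse,oral,10,mg/kg,mrt,5.44,h
mouse,oral,10,mg/kg,vss_over_f_per_kg,49.12,L/kg
mouse,oral,20,mg/kg,cmax,547.7,ng/mL
mouse,oral,20,mg/kg,tmax,1,h
mouse,oral,20,mg/kg,t_half,2.28,h
mouse,oral,20,mg/kg,auc_0_t,2308.8,ng.h/mL
mouse,oral,20,mg/kg,auc_0_inf,2310.8,ng.h/mL
mouse,oral,20,mg/kg,cl_over_f_per_kg,8.66,L/h/kg
mouse,oral,20,mg/kg,mrt,3.78,h
mouse,oral,20,mg/kg,vss_over_f_per_kg,32.73,L/kg
monkey,oral,3,mg/kg,cmax,1.5,ng/mL
monkey,oral,3,mg/kg,tmax,5,h
monkey,oral,3,mg/kg,t_half,2.86,h
monkey,oral,3,mg/kg,auc_0_t,11.7,ng.h/mL
monkey,oral,3,mg/kg,auc_0_inf,15.0,ng.h/mL
monkey,oral,3,mg/kg,bioavailability,0.35,%
monkey,oral,3,mg/kg,cl_over_f_per_kg,200.4,L/h/kg
monkey,oral,3,mg/kg,mrt,8.23,h
monkey,oral,3,mg/kg,vss_over_f_per_kg,1649.8,L/kg
monkey,oral,10,mg/kg,cmax,8.4,ng/mL
monkey,oral,10,mg/kg,tmax,3,h
monkey,oral,10,mg/kg,t_half,13.96,h
monkey,oral,10,mg/kg,auc_0_t,93.8,ng.h/mL
monkey,oral,10,mg/kg,auc_0_inf,107.9,ng.h/mL
monkey,oral,10,mg/kg,bioavailability,0.76,%
monkey,oral,10,mg/kg,cl_over_f_per_kg,92.69,L/h/kg
monkey,oral,10,mg/kg,mrt,17.06,h
monkey,oral,10,mg/kg,vss_over_f_per_kg,1581.6,L/kg
monkey,oral,30,mg/kg,cmax,18.5,ng/mL
monkey,oral,30,mg/kg,tmax,6,h
monkey,oral,30,mg/kg,t_half,15.96,h
monkey,oral,30,mg/kg,auc_0_t,348.8,ng.h/mL
monkey,oral,30,mg/kg,auc_0_inf,370.6,ng.h/mL
monkey,oral,30,mg/kg,bioavailability,0.87,%
monkey,oral,30,mg/kg,cl_over_f_per_kg,80.95,L/h/kg
monkey,oral,30,mg/kg,mrt,17.50,h
monkey,oral,30,mg/kg,vss_over_f_per_kg,1417.0,L/kg
monkey,intravenous,3,mg/kg,cmax,3868.0,ng/mL
monkey,intravenous,3,mg/kg,t_half,13.17,h
monkey,intravenous,3,mg/kg,auc_0_t,4722.9,ng.h/mL
monkey,intravenous,3,mg/kg,auc_0_inf,4802.7,ng.h/mL
monkey,intravenous,3,mg/kg,cl,2.811,L/h
monkey,intravenous,3,mg/kg,mrt,4.11,h
monkey,intravenous,3,mg/kg,vss,11.55,L
human,oral,20,mg,cmax,0.29,ng/mL
human,oral,20,mg,tmax,1,h
human,oral,20,mg,t_half,3.89,h
human,oral,20,mg,auc_0_t,2.07,ng.h/mL
human,oral,20,mg,auc_0_inf,2.70,ng.h/mL
human,oral,20,mg,cl_over_f_per_kg,105.8,L/h/kg
human,oral,20,mg,mrt,8.24,h
human,oral,20,mg,vss_over_f_per_kg,871.0,L/kg
human,oral,30,mg,cmax,0.40,ng/mL
human,oral,30,mg,tmax,1,h
human,oral,30,mg,t_half,5.69,h
human,oral,30,mg,auc_0_t,2.42,ng.h/mL
human,oral,30,mg,auc_0_inf,3.48,ng.h/mL
human,oral,30,mg,cl_over_f_per_kg,123.3,L/h/kg
human,oral,30,mg,mrt,9.39,h
human,oral,30,mg,vss_over_f_per_kg,1157.9,L/kg
human,oral,40,mg,cmax,0.45,ng/mL
human,oral,40,mg,tmax,4,h
human,oral,40,mg,t_half,12.91,h
human,oral,40,mg,auc_0_t,3.66,ng.h/mL
human,oral,40,mg,auc_0_inf,4.11,ng.h/mL
human,oral,40,mg,cl_over_f_per_kg,91.83,L/h/kg
human,oral,40,mg,mrt,16.55,h
human,oral,40,mg,vss_over_f_per_kg,1520.1,L/kg
human,oral_double,30,mg,cmax,0.48,ng/mL
human,oral_double,30,mg,tmax,27,h
human,oral_double,30,mg,t_half,18.86,h
human,oral_double,30,mg,auc_0_t,5.89,ng.h/mL
human,oral_double,30,mg,auc_0_inf,8.64,ng.h/mL
human,oral_double,30,mg,cl_over_f_per_kg,99.26,L/h/kg
human,oral_double,30,mg,mrt,45.18,h
human,oral_double,30,mg,vss_over_f_per_kg,4484.1,L/kg
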