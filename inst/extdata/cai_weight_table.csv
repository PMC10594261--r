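"item","label","type","group","level","points","sp1","sp2","sp3"
1,"own COVID-19 symptoms without diagnosis","own_infection",1,1,1,TRUE,TRUE,TRUE
2,"own COVID-19 diagnosis","own_infection",1,1,3,TRUE,TRUE,TRUE
3,"own COVID-19 course: mild","own_infection",1,1,3,FALSE,TRUE,TRUE
3,"own COVID-19 course: severe","own_infection",1,2,4,FALSE,TRUE,TRUE
3,"own COVID-19 course: hospitalised","own_infection",1,3,5,FALSE,TRUE,TRUE
4,"lives alone","living_alone",2,1,1,TRUE,TRUE,TRUE
5,"household member COVID-19 symptoms","household_infection",3,1,1,TRUE,TRUE,TRUE
6,"household member COVID-19 diagnosis","household_infection",3,1,2,TRUE,TRUE,TRUE
7,"household member severe course/hospitalised","household_infection",3,1,2,FALSE,TRUE,TRUE
8,"close contact died of COVID-19","bereavement",4,1,3,TRUE,TRUE,TRUE
9,"quarantine","quarantine",5,1,1,TRUE,TRUE,TRUE
10,"daily activities changed","activity_change",6,1,1,TRUE,TRUE,TRUE
11,"inside for prolonged periods","confinement",7,1,1,TRUE,FALSE,FALSE
12,"no outdoor space at home","no_outdoor_space",8,1,1,TRUE,TRUE,TRUE
13,"income decreased","financial",9,1,1,TRUE,TRUE,TRUE
14,"lost job","financial",9,1,2,TRUE,TRUE,TRUE
15,"serious financial problems","financial",9,1,2,FALSE,TRUE,TRUE
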