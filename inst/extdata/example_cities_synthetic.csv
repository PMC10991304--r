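city_id,province,year,area_1000ha,grain_yield_kg_ha
CC_demo_01,Henan,2011,120.5,6200
CC_demo_01,Henan,2012,118.0,6450
CC_demo_02,Shandong,2011,95.2,5900
CC_demo_02,Shandong,2012,97.8,6100
NC_demo_01,Shaanxi,2011,40.3,4100
NC_demo_01,Shaanxi,2012,NA,NA
SC_demo_01,Jiangsu,2011,75.0,5300
SC_demo_01,Jiangsu,2012,76.4,5450
SC_demo_02,Chongqing,2011,0,0
SC_demo_02,Chongqing,2012,0,0
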