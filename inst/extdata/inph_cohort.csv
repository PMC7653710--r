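group,gender,age,weight_kg,height_cm,bmi_printed,homa_ir,t2d,hypertension,abeta,apoe
BMI<25,Female,67,70,170,24.2,0.6,FALSE,FALSE,positive,3/4
BMI<25,Male,79,65,168,23,2.7,FALSE,FALSE,positive,3/4
BMI<25,Male,75,56,159,22.2,0.7,FALSE,TRUE,positive,4/4
BMI<25,Female,71,60,158,24,1.9,FALSE,FALSE,positive,3/3
BMI>30,Female,71,87,160,34,4.9,FALSE,FALSE,positive,3/4
BMI>30,Male,81,102,171,34.9,7,FALSE,FALSE,positive,3/3
BMI>30,Male,69,80,160,31.3,3.4,FALSE,TRUE,positive,3/3
BMI>30+T2D,Male,72,98,170,33.9,14.1,TRUE,TRUE,positive,3/3
BMI>30+T2D,Male,73,90,173,30.1,4.7,TRUE,TRUE,positive,3/4
BMI>30+T2D,Male,73,92,162,35.1,4.5,TRUE,TRUE,positive,3/3
BMI>30+T2D,Female,75,92,155,38.3,16.8,TRUE,TRUE,positive,3/4
BMI>30+T2D,Male,67,82,165,30.1,5.9,TRUE,TRUE,positive,3/4
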