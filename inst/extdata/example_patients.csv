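patient_id,sex,age_years,parameter,value
synth001,male,7,height,113.457261290599
synth001,male,7,weight,53.0480915359398
synth001,male,7,bmi,41.8729239297626
synth001,male,7,head_circumference,60.3861960427105
synth001,male,7,sitting_height,73.4287305086694
synth001,male,7,leg_length,36.4531391530443
synth001,male,7,arm_span,93.7175953540756
synth001,male,7,relative_sitting_height,75.9033247400807
synth001,male,7,foot_length,20.0906569349945
synth002,female,7.07306955615059,height,85.0370509758999
synth002,female,7.07306955615059,weight,16.5282906096281
synth002,female,7.07306955615059,bmi,14.7196649352784
synth002,female,7.07306955615059,head_circumference,48.4133922511327
synth002,female,7.07306955615059,sitting_height,53.8134271216711
synth002,female,7.07306955615059,leg_length,21.6649244436556
synth002,female,7.07306955615059,arm_span,67.3764838625735
synth002,female,7.07306955615059,relative_sitting_height,60.1194883211585
synth002,female,7.07306955615059,foot_length,13.0473993573452
synth003,male,16,height,129.803674814191
synth003,male,16,weight,46.5439784013057
synth003,male,16,bmi,28.6614863369867
synth003,male,16,head_circumference,59.1742249974787
synth003,male,16,sitting_height,82.5937352494237
synth003,male,16,leg_length,37.4496791244112
synth003,male,16,arm_span,106.171668562084
synth003,male,16,relative_sitting_height,65.3775094107978
synth003,male,16,foot_length,20.6204500248687
synth004,female,1.26721305400133,height,62.7155274878457
synth004,female,1.26721305400133,weight,8.06751293379425
synth004,female,1.26721305400133,bmi,16.2747049413338
synth004,female,1.26721305400133,head_circumference,44.433696357008
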