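subject_id,species,first_task,training_errors,training_trials,task1_errors,task1_trials,task1_reached,task2_presented,task2_errors,task2_trials,task2_reached,task1b_presented,task1b_errors,task1b_trials,task1b_reached,note
No. 2,macaw,trays,23,77,20,47,true,true,33,100,false,false,NA,NA,NA,
No. 4,macaw,trays,6,18,20,45,true,true,21,68,true,true,0,10,true,
Green,caique,trays,17,49,64,134,true,true,51,100,false,false,NA,NA,NA,
Red,caique,trays,5,27,57,133,true,true,0,9,true,true,0,10,true,transfer criterion met spontaneously at trial 9 (first nine correct; first error on trial 10)
No. 5,macaw,gaps,13,40,24,67,true,true,11,38,true,true,5,10,false,
No. 8,macaw,gaps,4,18,90,200,false,false,NA,NA,NA,false,NA,NA,NA,failed initial task within the 200-trial cap
Gold,caique,gaps,0,7,10,32,true,true,20,46,true,true,3,10,false,
Purple,caique,gaps,5,19,93,200,false,false,NA,NA,NA,false,NA,NA,NA,failed initial task within the 200-trial cap
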