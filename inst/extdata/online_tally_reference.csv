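model,subject,visual_T,visual_C,auditory_T,auditory_C,cognitive_T,cognitive_C,focused_T,focused_C,printed_accuracy_pct
gru_eegnet,1,65,52,150,72,100,69,608,486,73.56
gru_eegnet,2,55,44,180,86,130,76,576,435,68.12
gru_eegnet,3,60,47,180,91,110,81,648,486,70.64
gru_eegnet,4,65,54,165,71,120,83,582,479,73.71
gru_eegnet,5,60,51,150,69,130,79,617,495,72.52
eegnet,1,60,49,165,76,130,79,584,425,66.99
eegnet,2,65,51,150,76,120,75,612,413,64.94
eegnet,3,50,41,195,94,110,73,638,456,66.87
eegnet,4,55,46,180,89,120,82,596,421,67.09
eegnet,5,60,47,180,85,110,71,629,437,65.37
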