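model,mean_iou,val_loss,train_loss
CUMedVision,0.973,0.047,0.008
U-Net,0.594,0.410,0.409
DeepLabv3,0.989,0.011,0.005
ResU-Net-18,0.989,0.006,0.004
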