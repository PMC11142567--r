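# Aliases for internal primitives exercised directly by the tests.

conv2d_forward <- ultraseg:::conv2d_forward
conv2d_backward <- ultraseg:::conv2d_backward
convtranspose2_forward <- ultraseg:::convtranspose2_forward
convtranspose2_backward <- ultraseg:::convtranspose2_backward
bn_params <- ultraseg:::bn_params
bn_state <- ultraseg:::bn_state
bn_forward <- ultraseg:::bn_forward
bn_backward <- ultraseg:::bn_backward
res_block_params <- ultraseg:::res_block_params
res_block_state <- ultraseg:::res_block_state
res_block_forward <- ultraseg:::res_block_forward
seg_forward <- ultraseg:::seg_forward
seg_backward <- ultraseg:::seg_backward
align_grads <- ultraseg:::align_grads
adam_init <- ultraseg:::adam_init
adam_step <- ultraseg:::adam_step
batch_combined_loss <- ultraseg:::batch_combined_loss
batch_combined_loss_grad <- ultraseg:::batch_combined_loss_grad
stack_images <- ultraseg:::stack_images
stack_masks <- ultraseg:::stack_masks
pcbam_forward <- ultraseg:::pcbam_forward
pcbam_backward <- ultraseg:::pcbam_backward
swa_forward <- ultraseg:::swa_forward
swa_backward <- ultraseg:::swa_backward
cam_params <- ultraseg:::cam_params
sam_params <- ultraseg:::sam_params
pam_params <- ultraseg:::pam_params
mean_batch_dice <- ultraseg:::mean_batch_dice
serialize_config <- ultraseg:::serialize_config
deserialize_config <- ultraseg:::deserialize_config
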