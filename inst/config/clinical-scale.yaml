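# Clinical-scale configuration: the hyperparameters used for full-size
# otoscopy footage (ResNet-class backbone capacity is approximated here by
# wider dense encoders on finer pooled features). Not exercised by the test
# suite; provided as the reference operating configuration.
seed: 1
scene:
  frame_size: [224, 224]
  frames_per_video_range: [135, 1200]   # 5-40 s at ~27-30 fps
dataset:
  n_train_normal: 60
  n_val_normal: 10
  n_val_abnormal: 10
  n_test_normal: 10
  n_test_abnormal: 10
detector:
  input_size: 224
  pool: 8
  hidden: 512
  steps: 5000
  batch_size: 128
  lr: 0.001
  momentum: 0.9
  weight_decay: 0.0001
embedder:
  patch_size: 224
  pool: 8
  hidden: 512
  dim: 128
  tau: 0.25
  steps: 5000
  batch_size: 60
  lr: 0.00001
  momentum: 0.0
  weight_decay: 0.00005
  objective: final
shift:
  kind: cj-wf
scoring:
  k: 2
  target_tpr: 0.9
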