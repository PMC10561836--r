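# Canonical simplified fruit-detector topology.
#
# Block kinds/kernels/strides and the concatenation wiring are fixed by the
# published layer placements; the channel widths below are the calibrated
# free parameters, frozen so that the assembled network reproduces the
# published totals (1.8M parameters, 104 layers, and the exported-graph
# operator census). Block 30 concatenates the stride-32 downsample with the
# SPPF output (block 19); concatenating an intermediate 1x1 projection
# instead would leave the operator census unchanged but was rejected by the
# parameter calibration.
num_classes: 3
input_size: 640
depth_multiple: 0.33
width_multiple: 0.50
reg_max: 16
head_width: 64
detect_scales: [25, 28, 31]
blocks:
  - {index: 0,  kind: conv,     kernel: 3, stride: 2, in: 3,   out: 16}
  - {index: 1,  kind: conv,     kernel: 3, stride: 2, in: 16,  out: 32}
  - {index: 2,  kind: conv,     kernel: 1, stride: 1, in: 32,  out: 32}
  - {index: 3,  kind: conv,     kernel: 3, stride: 1, in: 32,  out: 32}
  - {index: 4,  kind: maxpool,  kernel: 2, stride: 2}
  - {index: 5,  kind: conv,     kernel: 1, stride: 1, in: 32,  out: 64}
  - {index: 6,  kind: conv,     kernel: 3, stride: 1, in: 64,  out: 64}
  - {index: 7,  kind: conv,     kernel: 1, stride: 1, in: 64,  out: 64}
  - {index: 8,  kind: concat,   sources: [5, 7]}
  - {index: 9,  kind: conv,     kernel: 1, stride: 1, in: 128, out: 64}
  - {index: 10, kind: maxpool,  kernel: 2, stride: 2}
  - {index: 11, kind: conv,     kernel: 1, stride: 1, in: 64,  out: 96}
  - {index: 12, kind: conv,     kernel: 3, stride: 1, in: 96,  out: 96}
  - {index: 13, kind: conv,     kernel: 1, stride: 1, in: 96,  out: 96}
  - {index: 14, kind: concat,   sources: [11, 13]}
  - {index: 15, kind: conv,     kernel: 1, stride: 1, in: 192, out: 128}
  - {index: 16, kind: maxpool,  kernel: 2, stride: 2}
  - {index: 17, kind: conv,     kernel: 1, stride: 1, in: 128, out: 128}
  - {index: 18, kind: conv,     kernel: 3, stride: 1, in: 128, out: 256}
  - {index: 19, kind: sppf,     kernel: 5, stride: 1, in: 256, out: 256, hidden: 128}
  - {index: 20, kind: upsample}
  - {index: 21, kind: concat,   sources: [20, 15]}
  - {index: 22, kind: conv,     kernel: 1, stride: 1, in: 384, out: 128}
  - {index: 23, kind: upsample}
  - {index: 24, kind: concat,   sources: [23, 9]}
  - {index: 25, kind: conv,     kernel: 1, stride: 1, in: 192, out: 64}
  - {index: 26, kind: conv,     kernel: 3, stride: 2, in: 64,  out: 64}
  - {index: 27, kind: concat,   sources: [26, 22]}
  - {index: 28, kind: conv,     kernel: 1, stride: 1, in: 192, out: 128}
  - {index: 29, kind: conv,     kernel: 3, stride: 2, in: 128, out: 128}
  - {index: 30, kind: concat,   sources: [29, 19]}
  - {index: 31, kind: conv,     kernel: 1, stride: 1, in: 384, out: 256}
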