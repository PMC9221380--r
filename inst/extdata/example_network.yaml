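# Two LC neurons coupled by a dendro-somatic NE synapse; neuron 1 is
# driven to ~20 Hz for one second.
kind: network
neurons:
  - {}
  - {}
edges:
  - {src: 1, dst: 2, mode: dendro_somatic, weight: 1}
protocols:
  - {onset_ms: 1000, duration_ms: 1000, amplitude: 10}
  - {}
duration_ms: 6000
seed: 1
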