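# Example run configuration: saturating flash on a 2.4x RK-overexpressing
# rod with arrestin oligomerization intact.
schema: 1
profile: amphibian
mutant: {RK: 2.4}
switches: {oligomerization_off: false}
protocol: {kind: flash, strength_Rstar: 118000, duration_s: 0.024, onset_s: 1}
horizon_s: 20
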