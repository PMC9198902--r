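# Fixed synthetic configuration for the end-to-end transfer property:
# 40-class JFPM grid, 8 channels, 6 blocks, 1.2 s decoding window,
# planted electrode rotation theta 0.5 with dry noise gain 3, 5 sub-bands.
nTargets: 40
nChannels: 8
nBlocks: 6
days: 2
epochLen: 1.4
signalAmp: 0.9
thetaDay: 0.2
thetaElectrode: 0.5
noiseGainDry: 3
ampGainDry: 0.8
nSubbands: 5
lengths: [1.2]
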