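roi,module
DMN_01,DMN
DMN_02,DMN
DMN_03,DMN
DMN_04,DMN
DMN_05,DMN
DMN_06,DMN
DMN_07,DMN
DMN_08,DMN
DMN_09,DMN
DMN_10,DMN
DMN_11,DMN
DMN_12,DMN
DMN_13,DMN
DMN_14,DMN
DMN_15,DMN
DMN_16,DMN
DMN_17,DMN
DMN_18,DMN
DMN_19,DMN
DMN_20,DMN
ECN_01,ECN
ECN_02,ECN
ECN_03,ECN
ECN_04,ECN
ECN_05,ECN
ECN_06,ECN
ECN_07,ECN
ECN_08,ECN
ECN_09,ECN
ECN_10,ECN
ECN_11,ECN
ECN_12,ECN
ECN_13,ECN
ECN_14,ECN
ECN_15,ECN
ECN_16,ECN
ECN_17,ECN
ECN_18,ECN
ECN_19,ECN
ECN_20,ECN
SN_01,SN
SN_02,SN
SN_03,SN
SN_04,SN
SN_05,SN
SN_06,SN
SN_07,SN
SN_08,SN
SN_09,SN
SN_10,SN
SN_11,SN
SN_12,SN
SN_13,SN
SN_14,SN
SN_15,SN
VN_01,VN
VN_02,VN
VN_03,VN
VN_04,VN
VN_05,VN
VN_06,VN
VN_07,VN
VN_08,VN
VN_09,VN
VN_10,VN
VN_11,VN
VN_12,VN
VN_13,VN
VN_14,VN
VN_15,VN
BGN_01,BGN
BGN_02,BGN
BGN_03,BGN
BGN_04,BGN
BGN_05,BGN
BGN_06,BGN
BGN_07,BGN
BGN_08,BGN
BGN_09,BGN
BGN_10,BGN
BGN_11,BGN
BGN_12,BGN
BGN_13,BGN
BGN_14,BGN
BGN_15,BGN
BGN_16,BGN
BGN_17,BGN
BGN_18,BGN
BGN_19,BGN
BGN_20,BGN
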