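# Maize (Zea mays) host parameter profile -- SCHEMA PLACEHOLDER.
# A host suitability run for overlap analysis needs a published maize
# parameterisation; enter its values below before use. Keys and units are
# identical to faw.params. The values shipped here are the package defaults
# and are NOT a maize calibration.

# DV0 = ...
# DV1 = ...
# DV2 = ...
# DV3 = ...
# SM0 = ...
# SM1 = ...
# SM2 = ...
# SM3 = ...
# TTCS = ...
# THCS = ...
# TTHS = ...
# THHS = ...
# SMDS = ...
# HDS = ...
# SMWS = ...
# HWS = ...
# PDD = ...
# irrigationRate = 2.5
# irrigationThreshold = 25
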