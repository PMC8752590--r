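# Fall armyworm (Spodoptera frugiperda) ecoclimatic parameter profile
# Units: temperatures degC; soil-moisture thresholds in index units
# (fraction of soil water holding capacity); stress rates per week
# (magnitudes; cold and dry stress accrue BELOW their thresholds);
# PDD in degree-days above DV0; irrigation in mm/day and mm/week.

DV0 = 12      # lower temperature threshold
DV1 = 25      # lower optimal temperature
DV2 = 30      # upper optimal temperature
DV3 = 36      # upper temperature threshold

SM0 = 0.15    # lower soil moisture threshold
SM1 = 0.8     # lower optimal soil moisture
SM2 = 1.5     # upper optimal soil moisture
SM3 = 2.0     # upper soil moisture threshold

TTCS = 8      # cold stress temperature threshold (weekly tmin)
THCS = 0.005  # cold stress accumulation rate
TTHS = 39     # heat stress temperature threshold (weekly tmax)
THHS = 0.0025 # heat stress accumulation rate
SMDS = 0.1    # dry stress soil moisture threshold
HDS = 0.005   # dry stress accumulation rate
SMWS = 2.0    # wet stress soil moisture threshold
HWS = 0.01    # wet stress accumulation rate

PDD = 400     # minimum annual degree-day sum per generation

irrigationRate = 2.5       # top-up irrigation, mm/day
irrigationThreshold = 25   # applied when weekly rain < this, mm/week
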