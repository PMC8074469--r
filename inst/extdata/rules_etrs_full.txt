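# Reference two-rule ETRS severity model, all five variables (the signalRMS
# antecedent sets were merged away by rule-base simplification)
RULE 1: IF (dominantFrequency IS high) AND (dominantMagnitude IS any value) AND (signalPeriod IS any value) AND (signalRMS IS any value) AND (powerGrowth IS any value) THEN (ETRS_score = 60.4 * dominantFrequency - 87 * dominantMagnitude + 14 * signalPeriod + 7.1 * signalRMS + 57.7 * powerGrowth - 2.19)
RULE 2: IF (dominantFrequency IS low) AND (dominantMagnitude IS low) AND (signalPeriod IS medium) AND (signalRMS IS any value) AND (powerGrowth IS medium) THEN (ETRS_score = -33.3 * dominantFrequency + 41.3 * dominantMagnitude + 10.8 * signalPeriod + 3.19 * signalRMS + 8.53 * powerGrowth + 55.7)
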