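# Reference two-rule ETRS severity model without the signalRMS variable
RULE 1: IF (dominantFrequency IS high) AND (dominantMagnitude IS any value) AND (signalPeriod IS any value) AND (powerGrowth IS any value) THEN (ETRS_score = 27.8 * dominantFrequency - 42.4 * dominantMagnitude + 22.4 * signalPeriod + 23.3 * powerGrowth + 8.7)
RULE 2: IF (dominantFrequency IS low) AND (dominantMagnitude IS low) AND (signalPeriod IS medium) AND (powerGrowth IS medium) THEN (ETRS_score = -10.8 * dominantFrequency + 53.5 * dominantMagnitude - 18.2 * signalPeriod + 14 * powerGrowth + 58.5)
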