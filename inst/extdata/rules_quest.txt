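# Reference two-rule QUEST severity model (normalized inputs, QUEST-score output)
RULE 1: IF (dominantFrequency IS high) AND (powerGrowth IS any value) THEN (QUEST_score = 4.66 * dominantFrequency - 8.52 * powerGrowth + 11.7)
RULE 2: IF (dominantFrequency IS low) AND (powerGrowth IS low) THEN (QUEST_score = -4.41 * dominantFrequency - 69.5 * powerGrowth + 47)
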