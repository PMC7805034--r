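# Deterministic planted-structure cohort: 26 patients in the 6/8/12 group
# layout with event counts 0/2/11 (the expected group rates), features
# well separated across the 9.3 / -48.9 thresholds and label positions
# placed at interior feature ranks so that the only systematic label signal
# is the two-threshold group structure itself.
planted_feature_cohort <- function() {
  # group 1: high blood volume; SUV change unconstrained by the model, with
  # several deep responders so no SUV-change cut separates outcomes cleanly
  g1 <- data.frame(group = 1L,
                   bv_pre = seq(10.3, 14.0, length.out = 6),
                   dsuv_max = c(-89, -87.5, -86.5, -86, -20, 5),
                   pcr = FALSE)
  # groups 2 and 3: low blood volume, interleaved bv ranks
  g2 <- data.frame(group = 2L,
                   bv_pre = seq(4.2, 8.2, length.out = 8),
                   dsuv_max = c(-44, -38, -33, -27, -20, -12, -3, 6),
                   pcr = FALSE)
  g2$pcr[c(3, 6)] <- TRUE                    # 2/8, interior dsuv ranks
  g3 <- data.frame(group = 3L,
                   bv_pre = seq(4.0, 8.4, length.out = 12),
                   dsuv_max = seq(-85, -54, length.out = 12),
                   pcr = TRUE)
  g3$pcr[6] <- FALSE                         # 11/12, interior dsuv rank
  rbind(g1, g2, g3)
}
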