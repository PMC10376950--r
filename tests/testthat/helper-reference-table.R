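# Published per-pair measurement table (nine BA pairs): four bronchus and
# four artery chord lengths, their printed means, areas and ratios. Used as
# fixed input for the measurement arithmetic checks.
published_pairs <- data.frame(
  pair = 1:9,
  BD1 = c(4.12, 7.24, 5.17, 7.24, 7.08, 5.06, 2.48, 6.22, 5.03),
  BD2 = c(3.00, 6.07, 5.27, 6.16, 7.04, 5.09, 3.00, 7.04, 5.04),
  BD3 = c(6.01, 7.16, 6.04, 8.18, 9.12, 5.20, 3.53, 7.00, 6.25),
  BD4 = c(6.01, 7.03, 7.07, 8.21, 8.12, 5.20, 4.15, 7.13, 4.35),
  ABD = c(4.79, 6.87, 5.89, 7.45, 7.84, 5.14, 3.29, 6.85, 5.17),
  AD1 = c(9.16, 9.11, 7.03, 10.06, 10.01, 8.04, 5.09, 9.03, 8.03),
  AD2 = c(8.17, 8.21, 7.05, 9.20, 16.00, 9.00, 5.14, 10.00, 7.04),
  AD3 = c(10.00, 11.02, 8.01, 11.03, 13.01, 8.03, 6.12, 13.01, 11.07),
  AD4 = c(10.17, 9.20, 8.06, 12.01, 14.11, 8.04, 5.05, 13.05, 9.14),
  AAD = c(9.38, 9.38, 7.54, 10.57, 13.29, 8.28, 5.35, 11.27, 8.82),
  BADR = c(0.51, 0.73, 0.78, 0.70, 0.59, 0.62, 0.62, 0.61, 0.59),
  BAr = c(12.00, 33.00, 26.00, 32.50, 42.00, 16.00, 5.00, 35.00, 18.00),
  AAr = c(61.00, 63.50, 41.50, 76.00, 125.00, 51.50, 18.00, 82.00, 49.50),
  BAAR = c(0.20, 0.52, 0.63, 0.43, 0.34, 0.31, 0.28, 0.43, 0.36)
)

# a printed value agrees with a computed value "to two decimals" when the
# computed value rounds to it under half-up or truncation (the source table
# mixes both conventions on exact ties)
agrees_2dp <- function(computed, printed) {
  abs(round_fixed(computed, 2, "half_up") - printed) < 1e-9 |
    abs(round_fixed(computed, 2, "truncate") - printed) < 1e-9
}
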