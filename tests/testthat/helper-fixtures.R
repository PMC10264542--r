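# Shared fixtures built in code.

# The experimentally anchored azide model: measured Kow 2.01 (pH 2.0)
# and 0.00034 (pH 8.0), pKa 4.65, kBT 0.593 kcal/mol.
azide_model <- function() new_partition_model(2.01, 0.00034, 4.65, 0.593)

azide_measurements <- function() {
  data.frame(pH = c(2, 8), Kow = c(2.01, 0.00034))
}

# The published 13-row distribution-coefficient table (printed precision).
published_q_table <- function() {
  data.frame(
    pH   = c(1, 2, 3, 4, 4.65, 6, 6.8, 7.1, 7.2, 7.4, 8, 9, 10),
    Q    = c(2.00955, 2.00551, 1.96599, 1.64239, 1.00517, 0.08627,
             0.01447, 0.00745, 0.00599, 0.00391, 0.00124, 0.00043,
             0.00035),
    logQ = c(0.303, 0.302, 0.294, 0.215, 0.002, -1.064, -1.840, -2.128,
             -2.223, -2.408, -2.908, -3.367, -3.457),
    dG   = c(-0.414, -0.413, -0.401, -0.294, -0.003, 1.453, 2.512,
             2.906, 3.035, 3.288, 3.970, 4.597, 4.721))
}

# The two published PAMPA plate rows (uM; standard geometry).
pampa_plate_rows <- function() {
  data.frame(pH = c(7.4, 8.0), C0 = c(3700.9, 3696.3),
             CD_t = c(3247.7, 3296.8), CA_t = c(675.5, 329.9),
             VD = 0.2, VA = 0.3, S = 0.3, t = 18000)
}

ecf <- function() compartment("ECF", 7.4)
cyt <- function() compartment("CYT", 7.2)
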