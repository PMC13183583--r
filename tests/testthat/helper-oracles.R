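# Independent oracles, written from the raw compartment solutions and
# elementary formulas rather than through the package's code paths.

# Ratio built from the two exponential compartment solutions directly:
# N(t) = Ne - (Ne - N0) e^{-kt}; C(t) = 1 - v N(t) (mass conservation).
oracle_ratio <- function(t, K_e, k, v = 1, N0 = 0) {
  Ce <- 1 / (1 + v * K_e)
  Ne <- K_e * Ce
  N <- Ne - (Ne - N0) * exp(-k * t)
  N / (1 - v * N)
}

# Plain FJC evaluation, no small-force series.
oracle_fjc <- function(F, dLc, l_K = 1.1, kT = 4.11) {
  b <- F * l_K / kT
  dLc * (1 / tanh(b) - 1 / b)
}

# Analytic mode of the Bell ramp rupture-force distribution.
oracle_bell_mode <- function(k0, delta_x, rate = 1, kT = 4.11) {
  (kT / delta_x) * log(rate * delta_x / (k0 * kT))
}

# CDF matching the Bell survival function, for KS tests.
oracle_bell_cdf <- function(F, k0, delta_x, rate = 1, kT = 4.11) {
  1 - exp(-(k0 * kT) / (rate * delta_x) * (exp(F * delta_x / kT) - 1))
}

# mCherry-like two-state ramp settings reused across detection tests.
mcherry_ramp_spec <- function(seed, noise_sd = 1) {
  ramp_sim_spec(noise_sd = noise_sd, seed = seed)
}

noise_only_ramp_spec <- function(seed, noise_sd = 2) {
  ramp_sim_spec(states = data.frame(k0 = numeric(0), delta_x = numeric(0),
                                    dLc = numeric(0)),
                noise_sd = noise_sd, seed = seed)
}

# Hand-written PDB fixture text: two residues with A/B altlocs on CA of
# residue 1 (occupancies 0.3/0.7) and two MODEL blocks with shifted z.
write_altloc_ensemble_pdb <- function(path) {
  atom <- function(serial, name, alt, resno, x, y, z, occ) {
    # strict PDB columns: name 13-16, altloc 17, resname 18-20, chain 22
    sprintf("ATOM  %5d %s%1sALA A%4d    %8.3f%8.3f%8.3f%6.2f  0.00           %s",
            serial, sprintf(" %-3s", name), alt, resno, x, y, z, occ,
            substr(name, 1, 1))
  }
  lines <- c(
    "MODEL        1",
    atom(1, "N", " ", 1, 0, 0, 0, 1),
    atom(2, "CA", "A", 1, 1.5, 0, 0, 0.30),
    atom(3, "CA", "B", 1, 1.5, 0.5, 0, 0.70),
    atom(4, "C", " ", 1, 2.5, 0, 0, 1),
    atom(5, "O", " ", 1, 2.5, 1.2, 0, 1),
    atom(6, "N", " ", 2, 3.8, 0, 0, 1),
    atom(7, "CA", " ", 2, 4.8, 0, 0, 1),
    atom(8, "C", " ", 2, 5.8, 0, 0, 1),
    atom(9, "O", " ", 2, 5.8, 1.2, 0, 1),
    "ENDMDL",
    "MODEL        2",
    atom(1, "N", " ", 1, 0, 0, 9, 1),
    atom(2, "CA", "A", 1, 1.5, 0, 9, 0.30),
    atom(3, "CA", "B", 1, 1.5, 0.5, 9, 0.70),
    atom(4, "C", " ", 1, 2.5, 0, 9, 1),
    atom(5, "O", " ", 1, 2.5, 1.2, 9, 1),
    atom(6, "N", " ", 2, 3.8, 0, 9, 1),
    atom(7, "CA", " ", 2, 4.8, 0, 9, 1),
    atom(8, "C", " ", 2, 5.8, 0, 9, 1),
    atom(9, "O", " ", 2, 5.8, 1.2, 9, 1),
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}
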