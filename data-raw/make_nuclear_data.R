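# Generates the plain-text nuclear data shipped in inst/extdata.
#
# The pointwise cross sections are simplified evaluated-data emulations:
# 1/v capture plus a single Breit-Wigner resonance for Au-197(n,g) and
# Mn-55(n,g), and a threshold table for Al-27(n,a)Na-24 (effective threshold
# 3.4 MeV).  Thermal (2200 m/s) values and resonance integrals are set to the
# accepted magnitudes (Au: 98.65 b, RI ~ 1550 b; Mn: 13.3 b, RI ~ 14 b) so the
# foil ordering and conditioning of the response matrix are realistic.  The
# H*(10) coefficients are the ICRP Publication 74 neutron values, extended
# flat below 1e-9 MeV and smoothly above 20 MeV so the package energy grid
# (1e-20 to 30 MeV) is covered without extrapolation.  Kerma coefficients for
# ICRU soft tissue (boron at the 25 ppm reference concentration, nitrogen
# capture, hydrogen recoil) are computed from number densities, 1/v or elastic
# cross sections, and reaction Q-values.
#
# Run from the repository root:  Rscript data-raw/make_nuclear_data.R

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

E_TH <- 2.53e-8   # MeV, 2200 m/s reference energy
MEV_J <- 1.602176634e-13
AVOGADRO <- 6.02214076e23

write_xs <- function(path, E, sigma, comment) {
  stopifnot(all(diff(E) > 0), all(sigma >= 0))
  con <- file(path, "w")
  writeLines(c(paste("#", comment),
               "# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)",
               "energy_MeV,value"), con)
  write.table(data.frame(E = signif(E, 8), v = signif(sigma, 6)), con,
              sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
}

# log grid with extra density around a resonance
xs_grid <- function(E_res = NULL, gamma = NULL) {
  E <- 10^seq(-20, log10(30), length.out = 90)
  if (!is.null(E_res)) {
    local <- E_res + gamma * seq(-30, 30, length.out = 41)
    E <- sort(unique(c(E, local[local > 0], E_res)))
  }
  E
}

breit_wigner <- function(E, E_res, gamma, peak) {
  peak / (1 + ((E - E_res) / (gamma / 2))^2)
}

# --- Au-197(n,g)Au-198: 1/v (98.65 b at 2200 m/s) + 4.9 eV resonance -------
E <- xs_grid(4.9e-6, 1.4e-7)
sigma <- 98.65 * sqrt(E_TH / E) +
  breit_wigner(E, 4.9e-6, 1.4e-7, 30000) + 0.08
write_xs("inst/extdata/xs_au197_ng.csv", E, sigma,
         "Au-197(n,gamma)Au-198 pointwise cross section, barns")

# --- Mn-55(n,g)Mn-56: 1/v (13.3 b) + 337 eV resonance ----------------------
E <- xs_grid(3.37e-4, 2.2e-5)
sigma <- 13.3 * sqrt(E_TH / E) +
  breit_wigner(E, 3.37e-4, 2.2e-5, 140) + 0.003
write_xs("inst/extdata/xs_mn55_ng.csv", E, sigma,
         "Mn-55(n,gamma)Mn-56 pointwise cross section, barns")

# --- Al-27(n,a)Na-24: threshold reaction, zero below 3.4 MeV ----------------
E <- c(1e-20, 1e-10, 1e-2, 1, 3.4,
       3.6, 4.0, 4.5, 5, 5.5, 6, 6.5, 7, 7.5, 8, 8.5, 9, 9.5, 10,
       11, 12, 13, 14, 15, 17, 20, 25, 30)
sigma <- c(0, 0, 0, 0, 0,
           5e-4, 6e-3, 1.5e-2, 3.1e-2, 5.0e-2, 7.1e-2, 8.6e-2, 9.8e-2,
           1.06e-1, 1.12e-1, 1.17e-1, 1.20e-1, 1.21e-1, 1.21e-1,
           1.18e-1, 1.11e-1, 1.00e-1, 8.5e-2, 7.0e-2, 5.5e-2, 4.2e-2,
           3.0e-2, 2.3e-2)
write_xs("inst/extdata/xs_al27_na.csv", E, sigma,
         "Al-27(n,alpha)Na-24 pointwise cross section, barns; threshold 3.4 MeV")

# --- ICRP 74 neutron fluence-to-H*(10) coefficients, pSv cm2 ----------------
icrp <- data.frame(
  E = c(1e-9, 1e-8, 2.53e-8, 1e-7, 2e-7, 5e-7, 1e-6, 2e-6, 5e-6,
        1e-5, 2e-5, 5e-5, 1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3,
        1e-2, 2e-2, 3e-2, 5e-2, 7e-2, 1e-1, 1.5e-1, 2e-1, 3e-1,
        5e-1, 7e-1, 9e-1, 1, 1.2, 2, 3, 4, 5, 6, 7, 8, 9, 10,
        12, 14, 15, 16, 18, 20),
  h = c(6.60, 9.00, 10.6, 12.9, 13.5, 13.6, 13.3, 12.9, 12.0,
        11.3, 10.6, 9.90, 9.40, 8.90, 8.30, 7.90, 7.70, 8.00,
        10.5, 16.6, 23.7, 41.1, 60.0, 88.0, 132, 170, 233,
        322, 375, 400, 416, 425, 420, 412, 408, 405, 400, 405,
        409, 420, 440, 480, 520, 540, 555, 570, 600))
# flat extension below the table; smooth continuation 20 -> 30 MeV
icrp <- rbind(data.frame(E = 1e-20, h = 6.60), icrp,
              data.frame(E = c(25, 30), h = c(625, 650)))
write_xs("inst/extdata/h_star_neutron.csv", icrp$E, icrp$h,
         "Neutron fluence-to-ambient-dose-equivalent H*(10), pSv cm2 (ICRP 74; extended below 1e-9 and above 20 MeV)")

# --- kerma coefficients for ICRU soft tissue, Gy cm2 ------------------------
# boron: 10B(n,a)7Li at the 25 ppm reference blood concentration,
# sigma0 = 3837 b (1/v), mean charged-particle energy 2.33 MeV
n_b10 <- 25e-6 / 10.013 * AVOGADRO          # atoms per g tissue
E <- 10^seq(-20, log10(30), length.out = 70)
k_b <- n_b10 * 3837e-24 * sqrt(E_TH / E) * 2.33 * MEV_J * 1000
write_xs("inst/extdata/kerma_boron_25ppm.csv", E, k_b,
         "Boron dose coefficient at 25 ppm 10B, Gy cm2 per unit fluence")

# nitrogen: 14N(n,p)14C, sigma0 = 1.83 b (1/v), Q = 0.62 MeV, w_N = 0.026
n_n14 <- 0.026 / 14.003 * AVOGADRO
k_n <- n_n14 * 1.83e-24 * sqrt(E_TH / E) * 0.62 * MEV_J * 1000
write_xs("inst/extdata/kerma_nitrogen.csv", E, k_n,
         "Nitrogen 14N(n,p)14C dose coefficient in ICRU soft tissue, Gy cm2")

# hydrogen: elastic recoil, mean energy transfer E/2, w_H = 0.101
# sigma_el(E): flat 20.4 b at low energy, falling to ~4 b at 1 MeV
n_h <- 0.101 / 1.008 * AVOGADRO
sigma_h <- pmin(20.4, pmax(20.4 / sqrt(1 + 25 * E), 0.3))
k_h <- n_h * sigma_h * 1e-24 * (E / 2) * MEV_J * 1000
k_h <- pmax(k_h, 1e-40)            # keep strictly positive for log-log interp
write_xs("inst/extdata/kerma_hydrogen.csv", E, k_h,
         "Hydrogen elastic-recoil dose coefficient in ICRU soft tissue, Gy cm2")

message("wrote inst/extdata nuclear data files")
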