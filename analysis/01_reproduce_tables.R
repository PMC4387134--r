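#!/usr/bin/env Rscript
# Recompute the experiment's headline numbers from the recorded frame
# bookkeeping embedded in the package (no simulation involved): the
# high-quality-image ratios per model and velocity, their quadratic and
# Gaussian-exponential velocity fits, the fur/plaster decay quotient, and
# the landmark-imprecision (RpV) refits with the between-model rank test.

suppressPackageStartupMessages(library(tofcow))

out_dir <- "results/tables"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rep <- fixture_report()
write_report(rep, out_dir)

cat("High-quality-image ratios (N/C):\n")
print(rep$table1, row.names = FALSE)

cat("\nVelocity fits over ordinal x = 1..4 (0, 10, 20, 30 cm/s):\n")
for (m in c("plaster", "fur")) {
  cat(sprintf("-- %s\n", m))
  print(rep$hqi_fits[[m]]$quadratic)
  print(rep$hqi_fits[[m]]$gaussian)
}
cat(sprintf("\nQuadratic-coefficient quotient fur/plaster: %.4g\n",
            rep$alpha_ratio))
cat("  (image quality decays about four times faster with fur)\n")

cat("\nRpV refits per body part (quadr. coefficient, RMSD, R^2):\n")
print(rep$table4[, c("model", "body_part", "coeff", "rmsd", "r_squared")],
      row.names = FALSE, digits = 3)
cat(sprintf("\nCoefficient medians (2-decimal convention): plaster %.3f, fur %.2f\n",
            rep$coeff_medians["plaster"], rep$coeff_medians["fur"]))
cat("Between-model rank-sum test of the quadratic coefficients:\n")
print(rep$coeff_test)
cat("  RpV grows quadratically only for the fur-covered model;\n")
cat("  the plaster coefficients hover at zero (linear growth).\n")
cat("\nTables written to", out_dir, "\n")
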