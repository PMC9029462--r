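#!/usr/bin/env Rscript
# Build the packaged film x method scenario grid and tabulate the
# ground-truth scripts: endpoints (with censoring), event schedules and
# friction signatures. This is the study design every later stage
# analyses blind.

suppressMessages(library(odftoolbox))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (film in film_ids()) for (method in odf_methods()) {
  sc <- build_scenario(film, method)
  rows[[length(rows) + 1]] <- data.frame(
    film = film, method = method,
    polymer = sc$film$polymer, mw_kda = sc$film$mw_kda,
    duration_s = sc$duration_s,
    true_endpoint_s = ifelse(sc$censored, NA, sc$true_endpoint_s),
    censored = sc$censored,
    n_events = length(sc$events),
    events = paste(vapply(sc$events, `[[`, character(1), "kind"),
                   collapse = "+"),
    cof_shape = if (is.null(sc$cof_signature)) NA_character_
                else sc$cof_signature$shape)
}
grid <- do.call(rbind, rows)
write.csv(grid, "results/01_scenario_grid.csv", row.names = FALSE)

cat("Scenario grid (endpoints in seconds; NA = censored at 180 s):\n\n")
print(grid, row.names = FALSE)
cat("\nKey features scripted from the study narrative:\n")
cat(" - P1/ocm detaches a fragment at 24 s then shrinks progressively.\n")
cat(" - P2/ocm tears transiently (70/80/95 s corner, 105-160 s partial\n")
cat("   vertical) and re-coalesces: no persistent split, censored.\n")
cat(" - C1/C2 in the OCM only swell (palate adhesion): censored.\n")
cat(" - BTM friction signatures decline (CMC) or fluctuate (PVA) into\n")
cat("   a terminal plateau at the observed disintegration time.\n")
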