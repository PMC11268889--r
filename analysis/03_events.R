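#!/usr/bin/env Rscript
# Stage 3 -- pool the per-owl tables into the study-level analysis set.
#
# Applies the study's filtering rules on the way: perch landings made while
# loaded with prey are excluded from force analyses; hunting attempts whose
# preceding flight fits neither strategy window (> 1 s and < 5 s) stay in the
# table but are reported as the excluded fraction, and pre-hunt perch forces
# are only attached when the perch-to-strike gap is under 90 s.

suppressPackageStartupMessages(library(owlstrike))

in_dir <- "results/synthetic"
pop <- read.csv(file.path(in_dir, "population.csv"), stringsAsFactors = FALSE)

read_all <- function(prefix) {
  dplyr::bind_rows(lapply(pop$owl_id, function(id) {
    df <- read.csv(file.path(in_dir, paste0(prefix, "_", id, ".csv")),
                   stringsAsFactors = FALSE)
    df$owl_id <- id
    df$sex <- pop$sex[pop$owl_id == id]
    df
  }))
}

landings <- read_all("landings")
attempts <- read_all("attempts")
trips <- read_all("trips")

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.csv(landings, "results/tables/landings_all.csv", row.names = FALSE)
write.csv(attempts, "results/tables/attempts_all.csv", row.names = FALSE)
write.csv(trips, "results/tables/trips_all.csv", row.names = FALSE)

perch <- subset(landings, subtype == "perch" & !loaded_with_prey)
strike <- subset(landings, subtype == "strike")
cat("pooled:", nrow(landings), "landings ->", nrow(perch),
    "unloaded perch events,", nrow(strike), "strikes;",
    nrow(attempts), "attempts over", nrow(trips), "trips\n")
cat(sprintf("excluded strategy fraction: %.1f%%\n",
            100 * mean(attempts$strategy == "excluded")))
cat(sprintf("pre-hunt force attached (gap < 90 s): %d of %d attempts\n",
            sum(is.finite(attempts$prehunt_perch_force_N)), nrow(attempts)))
cat(sprintf("loaded-with-prey perch landings excluded: %d\n",
            sum(landings$loaded_with_prey, na.rm = TRUE)))
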