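# Independent brute-force oracle: recount UR/FC/NU, Nur/Ntaxa and Np by
# explicit set enumeration with base-R loops, no dplyr, no shared code with
# the pipeline under test.
brute_force_tally <- function(records) {
  recs <- unique(data.frame(informant = as.character(records$informant),
                            species = as.character(records$species),
                            category = as.character(records$category),
                            stringsAsFactors = FALSE))
  species <- sort(unique(recs$species))
  categories <- sort(unique(recs$category))
  sp <- data.frame(species = species, ur = 0L, fc = 0L, nu = 0L)
  for (i in seq_along(species)) {
    sub <- recs[recs$species == species[i], ]
    pairs <- unique(paste(sub$informant, sub$category, sep = "\r"))
    sp$ur[i] <- length(pairs)
    sp$fc[i] <- length(unique(sub$informant))
    sp$nu[i] <- length(unique(sub$category))
  }
  ct <- data.frame(category = categories, nur = 0L, ntaxa = 0L)
  for (i in seq_along(categories)) {
    sub <- recs[recs$category == categories[i], ]
    ct$nur[i] <- nrow(sub)
    ct$ntaxa[i] <- length(unique(sub$species))
  }
  cells <- list()
  for (s in species) for (cc in categories) {
    np <- length(unique(recs$informant[recs$species == s & recs$category == cc]))
    if (np > 0) cells[[length(cells) + 1L]] <-
        data.frame(species = s, category = cc, np = np)
  }
  list(species = sp, categories = ct,
       cells = do.call(rbind, c(cells, list(make.row.names = FALSE))))
}

# a random small survey as a raw record data frame (base R only)
random_small_records <- function(n_informants = 20, n_species = 8,
                                 n_categories = 5, n_rows = 60) {
  data.frame(
    informant = sprintf("i%02d", sample.int(n_informants, n_rows, replace = TRUE)),
    species = sprintf("s%02d", sample.int(n_species, n_rows, replace = TRUE)),
    category = sprintf("c%02d", sample.int(n_categories, n_rows, replace = TRUE)),
    stringsAsFactors = FALSE)
}

# a random feasible margin set: per-species cells with positive Np and an FC
# drawn between max(Np) and sum(Np)
random_feasible_margins <- function(max_species = 8, max_categories = 6) {
  n_sp <- sample(1:max_species, 1)
  cells <- list(); fc <- integer(n_sp)
  for (s in seq_len(n_sp)) {
    n_cells <- sample(1:max_categories, 1)
    cats <- sample(sprintf("c%02d", 1:max_categories), n_cells)
    np <- sample(1:5, n_cells, replace = TRUE)
    fc_range <- max(np):sum(np)
    fc[s] <- fc_range[sample.int(length(fc_range), 1)]
    cells[[s]] <- data.frame(species = sprintf("s%02d", s),
                             category = cats, np = np)
  }
  list(cells = do.call(rbind, cells),
       fc = data.frame(species = sprintf("s%02d", seq_len(n_sp)), fc = fc))
}
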