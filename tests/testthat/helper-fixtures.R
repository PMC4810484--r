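# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small community: 6 genomes, 3 degraders, light decoy load
mini_community <- function() fixture("mini_community", function() {
  generate_community(community_config(
    n_genomes = 6, degrader_fraction = 0.5, n_decoys_per_genome = 25,
    n_near_decoys = 2, plasmid_probability = 0.4, seed = 42))
})

# full pipeline run on the small community (bootstrap scaled down)
mini_report <- function() fixture("mini_report", function() {
  run_pipeline(mini_community(),
               pipeline_config(phylo = list(markers = c("KshA", "HsaA",
                                                        "HsaC", "HsaD"),
                                            bootstrap = 25), seed = 42),
               out_dir = file.path(tempdir(), "mini_run_a"))
})

# a small protein family for alignment/HMM tests
toy_family <- function() fixture("toy_family", function() {
  set.seed(9)
  anc <- random_protein(140)
  setNames(vapply(1:5, function(i)
    as.character(evolve_sequence(anc, 0.75)), character(1)),
    paste0("fam", 1:5))
})

# an equal-rate two-letter toy HMM exercised by enumeration oracles
toy_hmm <- function(m = 2) {
  ent <- rep(1 / m, m)
  exitp <- c(rep(1 / (m + 1), m - 1), 1)
  tMM <- tMI <- tMD <- rep(0, m)
  for (k in seq_len(m - 1)) {
    tMM[k] <- 0.5 * (1 - exitp[k])
    tMI[k] <- 0.3 * (1 - exitp[k])
    tMD[k] <- 0.2 * (1 - exitp[k])
  }
  tIM <- c(rep(0.7, m - 1), 1); tII <- 1 - tIM
  tDM <- c(rep(0.6, m - 1), 1); tDD <- 1 - tDM
  E <- matrix(rep(c(0.8, 0.2), m), m, 2, byrow = TRUE)
  if (m > 1) E[2, ] <- c(0.3, 0.7)
  profile_hmm(E, list(tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
                      tDM = tDM, tDD = tDD, entry = ent, exitp = exitp),
              background = c(0.55, 0.45), alphabet = c("A", "C"))
}
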