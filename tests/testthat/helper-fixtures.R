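# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# a single small Complete genome (full Pseudomonas-type cluster with one
# complete and one partial IS element), scanned; reused across test files
fixture_scan <- function() {
  if (!is.null(.fixture_env$scan)) return(.fixture_env$scan)
  plan <- default_survey_plan()
  sv <- generate_survey(plan[plan$genome_id == "g04", ], seed = 11)
  sc <- scan_survey(sv$assemblies)
  .fixture_env$scan <- list(survey = sv, scan = sc)
  .fixture_env$scan
}

# mini two-genome survey: one clean genome + one with a marinobacter-type
# cluster and an alkK pseudogene
fixture_mini_survey <- function() {
  if (!is.null(.fixture_env$mini)) return(.fixture_env$mini)
  plan <- default_survey_plan()
  sv <- generate_survey(plan[plan$genome_id %in% c("g06", "g15"), ],
                        seed = 7)
  sc <- scan_survey(sv$assemblies)
  .fixture_env$mini <- list(survey = sv, scan = sc)
  .fixture_env$mini
}

# organization objects straight from label vectors (for similarity/grouping
# tests that do not need sequences)
org_from_labels <- function(labels) {
  structure(list(tokens = data.frame(label = labels,
                                     strand = rep("+", length(labels)),
                                     pseudogene = rep(FALSE, length(labels)),
                                     stringsAsFactors = FALSE),
                 anchor_offset = match("alkB", labels) - 1L,
                 string = paste0(labels, ">", collapse = ",")),
            class = "organization")
}

random_protein <- function(n, seed = NULL) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
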