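#' Candidate demographic scenarios for ABC comparison
#'
#' Two ready-made scenario sets mirroring the divergence hypotheses relevant
#' to a cherry accession panel. `"three_group"` covers the domestication of
#' cultivated Chinese cherry (CC) from wild Chinese cherry (WC) and wild
#' relatives (RC): (A) stepwise splits RC -> WC -> CC; (B) CC and WC splitting
#' independently from RC; (C) stepwise splits with a post-divergence
#' admixture pulse from RC into WC, the gene-flow variant. `"five_group"`
#' holds the single best-supported worldwide history (Microcerasus (MC)
#' diverging first, the European group (EC) second, the Chinese groups
#' diversifying recently), which the synthetic panel generator uses.
#'
#' Priors are uniform; size and time priors follow the credible ranges a
#' panel of this design can support (sizes of order 10^3..10^5, a recent
#' domestication split of order 10^3 years and a wild divergence of order
#' 10^4..10^5 years), with the mutation-rate prior `U(1e-4, 1e-3)` per locus
#' per generation and a 4-year generation time throughout.
#'
#' @param set `"three_group"` (default) or `"five_group"`.
#' @return Named list of `scenario` objects.
#' @export
demographic_scenarios <- function(set = c("three_group", "five_group")) {
  set <- match.arg(set)
  mu_prior <- c(1e-4, 1e-3)
  if (set == "three_group") {
    size_priors <- list(N_CC = c(500, 6000), N_WC = c(1000, 10000),
                        N_RC = c(5000, 83000))
    time_priors <- list(T_1 = c(1000, 6000),      # CC split, years
                        T_2 = c(12000, 100000))   # WC/RC split, years
    list(
      stepwise = scenario(
        "stepwise",
        demes = c(CC = 1530, WC = 5890, RC = 37500),
        events = list(ev_merge(2660, "CC", "WC"),
                      ev_merge(34200, "WC", "RC")),
        priors = c(size_priors, time_priors, list(mu = mu_prior))),
      independent = scenario(
        "independent",
        demes = c(CC = 1530, WC = 5890, RC = 37500),
        events = list(ev_merge(2660, "CC", "RC"),
                      ev_merge(34200, "WC", "RC")),
        priors = c(size_priors, time_priors, list(mu = mu_prior))),
      stepwise_admixture = scenario(
        "stepwise_admixture",
        demes = c(CC = 1530, WC = 5890, RC = 37500),
        events = list(ev_merge(2660, "CC", "WC"),
                      ev_admixture(15000, "WC", "RC", 0.3),
                      ev_merge(34200, "WC", "RC")),
        priors = c(size_priors,
                   list(T_1 = time_priors$T_1, T_3 = time_priors$T_2,
                        frac_2 = c(0.05, 0.5), mu = mu_prior))))
  } else {
    list(
      worldwide = scenario(
        "worldwide",
        demes = c(CC = 1530, WC = 5890, RC = 37500, EC = 1610, MC = 37300),
        events = list(ev_merge(2660, "CC", "WC"),
                      ev_merge(34200, "WC", "RC"),
                      ev_merge(1760000, "EC", "RC"),
                      ev_resize(1760000, "RC", 43900),
                      ev_merge(3520000, "MC", "RC")),
        priors = list(mu = mu_prior)))
  }
}

#' Generate a synthetic study-shaped accession panel
#'
#' Stands in for a field-collected panel: simulates sequences under a preset
#' demographic history and wraps them as an `aligned_dataset` with
#' population/subgroup/group metadata, plus a truth record sufficient to
#' regenerate the panel exactly.
#'
#' Presets:
#' \describe{
#' \item{`five_group`}{Five groups CC/WC/RC/EC/MC subdivided into 12
#'   populations across four geographic regions (NEC, LFZ, YGP, QLM), group
#'   sample sizes 331/204/174/120/79 (a 912-accession panel). History: MC
#'   diverges first (3.52 Ma), EC second (1.76 Ma), WC from RC 34,200 years
#'   ago, CC domesticated 2,660 years ago; populations within groups split
#'   recently. Deep divergence makes recurrent substitution likely, so the
#'   finite-sites Jukes-Cantor model is used, on an ITS-sized 710-bp locus.}
#' \item{`three_group`}{The Chinese groups CC/WC/RC only, 10 populations,
#'   sizes 331/204/174, shallow history (infinite-sites).}
#' \item{`toy`}{Two demes of 10 samples each on a 100-bp locus.}
#' }
#'
#' @param preset `"five_group"`, `"three_group"` or `"toy"`.
#' @param seed Integer seed (the panel is a deterministic function of it).
#' @param mu Mutation rate per locus per generation (default `2e-4`, within
#'   the customary `U(1e-4, 1e-3)` prior and matching the nucleotide
#'   diversities such panels show).
#' @param scale Multiplier on all sample sizes (default 1); use < 1 for
#'   quick runs.
#' @return A `simulated_dataset`.
#' @export
make_fixture <- function(preset = c("five_group", "three_group", "toy"),
                         seed = 1L, mu = 2e-4, scale = 1) {
  preset <- match.arg(preset)
  set.seed(seed)
  sz <- function(x) stats::setNames(pmax(2L, as.integer(round(x * scale))),
                                    names(x))

  if (preset == "toy") {
    sc <- scenario("toy",
                   demes = c(popA = 5000, popB = 5000),
                   events = list(ev_merge(40000, "popB", "popA")))
    n <- sz(c(popA = 10, popB = 10))
    gen <- simulate_genealogy(sc, n)
    return(mutate_sequences(gen, L = 100L, mu = mu / 100, sc = sc,
                            model = "infinite_sites",
                            truth = list(preset = preset, seed = seed,
                                         mu = mu, sample_sizes = n)))
  }

  regions <- c(NEC = "NEC", LFZ = "LFZ", YGP = "YGP", QLM = "QLM")
  chinese_demes <- c("NEC-C" = 1530, "LFZ-C" = 1530, "YGP-C" = 1530,
                     "QLM-C" = 1530,
                     "LFZ-W" = 5890, "YGP-W" = 5890, "QLM-W" = 5890,
                     "LFZ-R" = 37500, "YGP-R" = 37500, "QLM-R" = 37500)
  chinese_groups <- c("NEC-C" = "CC", "LFZ-C" = "CC", "YGP-C" = "CC",
                      "QLM-C" = "CC",
                      "LFZ-W" = "WC", "YGP-W" = "WC", "QLM-W" = "WC",
                      "LFZ-R" = "RC", "YGP-R" = "RC", "QLM-R" = "RC")
  # populations coalesce within their group recently, then the groups follow
  # the domestication history: CC from WC 2660 yr, WC from RC 34,200 yr
  chinese_events <- list(
    ev_merge(800,  "NEC-C", "LFZ-C"), ev_merge(800,  "YGP-C", "LFZ-C"),
    ev_merge(800,  "QLM-C", "LFZ-C"),
    ev_merge(2660, "LFZ-C", "LFZ-W"),
    ev_merge(8000, "YGP-W", "LFZ-W"), ev_merge(8000, "QLM-W", "LFZ-W"),
    ev_merge(20000, "YGP-R", "LFZ-R"), ev_merge(20000, "QLM-R", "LFZ-R"),
    ev_merge(34200, "LFZ-W", "LFZ-R"))
  chinese_sizes <- c("NEC-C" = 80, "LFZ-C" = 120, "YGP-C" = 70, "QLM-C" = 61,
                     "LFZ-W" = 100, "YGP-W" = 60, "QLM-W" = 44,
                     "LFZ-R" = 80, "YGP-R" = 50, "QLM-R" = 44)
  chinese_subgroups <- sub("^([A-Z]+)-.*$", "\\1", names(chinese_demes))
  names(chinese_subgroups) <- names(chinese_demes)

  if (preset == "three_group") {
    sc <- scenario("three_group_panel", demes = chinese_demes,
                   events = chinese_events, groups = chinese_groups)
    n <- sz(chinese_sizes)
    gen <- simulate_genealogy(sc, n)
    ds <- mutate_sequences(gen, L = 710L, mu = mu / 710, sc = sc,
                           model = "infinite_sites",
                           truth = list(preset = preset, seed = seed,
                                        mu = mu, sample_sizes = n))
  } else {
    demes <- c(chinese_demes, EC = 1610, MC = 37300)
    groups <- c(chinese_groups, EC = "EC", MC = "MC")
    events <- c(chinese_events, list(
      ev_merge(1760000, "EC", "LFZ-R"),
      ev_resize(1760000, "LFZ-R", 43900),
      ev_merge(3520000, "MC", "LFZ-R")))
    sc <- scenario("five_group_panel", demes = demes, events = events,
                   groups = groups)
    n <- sz(c(chinese_sizes, EC = 120, MC = 79))
    gen <- simulate_genealogy(sc, n)
    ds <- mutate_sequences(gen, L = 710L, mu = mu / 710, sc = sc,
                           model = "jukes_cantor",
                           truth = list(preset = preset, seed = seed,
                                        mu = mu, sample_sizes = n))
  }
  ds$samples$subgroup <- ifelse(
    ds$samples$deme %in% names(chinese_subgroups),
    chinese_subgroups[ds$samples$deme], ds$samples$deme)
  ds$truth$scenario <- sc$name
  ds
}

#' Write a simulated dataset as FASTA + metadata (+ truth sidecar)
#'
#' Emits the same dialect [read_dataset()] reads, so synthetic panels can be
#' round-tripped through the file interface; the truth record is written as
#' a JSON sidecar.
#'
#' @param ds A `simulated_dataset` (or `aligned_dataset`).
#' @param stem Output path stem; writes `<stem>.fasta`, `<stem>.tsv` and,
#'   when a truth record exists, `<stem>.truth.json`.
#' @return The stem, invisibly.
#' @export
write_dataset <- function(ds, stem) {
  lines <- character(2L * nrow(ds$matrix))
  lines[c(TRUE, FALSE)] <- paste0(">", ds$samples$sample_id)
  lines[c(FALSE, TRUE)] <- apply(ds$matrix, 1L, paste, collapse = "")
  writeLines(lines, paste0(stem, ".fasta"))
  utils::write.table(ds$samples, paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ds$truth))
    jsonlite::write_json(ds$truth, paste0(stem, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read or write a scenario definition file
#'
#' Scenarios serialize to a small YAML document: deme sizes, an ordered
#' events list, the generation time, group labels and priors.
#'
#' @param sc A `scenario` (for writing).
#' @param path File path.
#' @return `read_scenario()` returns a `scenario`; `write_scenario()` the
#'   path, invisibly.
#' @export
write_scenario <- function(sc, path) {
  yaml::write_yaml(list(name = sc$name, demes = as.list(sc$demes),
                        events = sc$events,
                        generation_time_years = sc$generation_time_years,
                        groups = as.list(sc$groups),
                        priors = lapply(sc$priors, as.numeric)),
                   path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario(name = y$name, demes = unlist(y$demes),
           events = y$events,
           generation_time_years = y$generation_time_years %||% 4,
           groups = if (!is.null(y$groups)) unlist(y$groups) else NULL,
           priors = y$priors %||% list())
}
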