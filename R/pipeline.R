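#' Read a pipeline configuration
#'
#' The configuration is a small YAML document:
#' \preformatted{
#' input:
#'   fixture: five_group        # or fasta: path, metadata: path
#' indel_mode: simple_indel_coding
#' grouping: group              # hierarchy level for AMOVA / reports
#' seed: 1
#' n_sims: 1000                 # neutrality-test null simulations
#' n_boot: 200                  # mismatch bootstrap replicates
#' n_perm: 1000                 # AMOVA / Fst permutations
#' abc:
#'   enabled: false
#'   n_per_scenario: 2000
#'   retain: 0.01
#'   n_pods: 30
#' output_dir: results/run1
#' }
#'
#' @param path YAML file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A configuration list (as from YAML).
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$input) ||
      (is.null(cfg$input$fixture) && is.null(cfg$input$fasta)))
    stop("config needs input$fixture or input$fasta + input$metadata")
  if (!is.null(cfg$input$fasta)) {
    if (!file.exists(cfg$input$fasta)) stop("missing file: ", cfg$input$fasta)
    if (is.null(cfg$input$metadata) || !file.exists(cfg$input$metadata))
      stop("missing metadata file")
  }
  cfg$indel_mode <- cfg$indel_mode %||% "simple_indel_coding"
  cfg$grouping <- cfg$grouping %||% "group"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_sims <- as.integer(cfg$n_sims %||% 1000L)
  cfg$n_boot <- as.integer(cfg$n_boot %||% 200L)
  cfg$n_perm <- as.integer(cfg$n_perm %||% 1000L)
  cfg$abc <- cfg$abc %||% list(enabled = FALSE)
  cfg$abc$enabled <- isTRUE(cfg$abc$enabled)
  cfg$output_dir <- cfg$output_dir %||% "pipeline_out"
  structure(cfg, class = "pipeline_config")
}

# one master seed fans out to per-stage seeds so stages can be rerun alone
stage_seed <- function(master, stage) {
  offsets <- c(data = 11L, neutrality = 23L, mismatch = 37L, amova = 53L,
               fst = 67L, network = 79L, abc = 97L)
  (master * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full phylogeographic analysis pipeline
#'
#' Executes ingestion -> indel recoding -> haplotype collapsing -> distances
#' -> diversity/neutrality/mismatch reports -> AMOVA and pairwise Fst ->
#' median-joining network -> (optionally) ABC scenario choice, writing every
#' artifact plus a JSON run manifest (package version, config, per-stage
#' seeds) into the output directory. All randomness derives from the single
#' master seed, so a rerun with the same configuration is byte-identical.
#'
#' @param cfg A `pipeline_config` (or path to one).
#' @return List of result objects (invisibly also written to
#'   `cfg$output_dir`): `dataset`, `haplotypes`, `summary`, `diversity`,
#'   `amova`, `fst`, `network`, `abc` (NULL when disabled),
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_step <- function(...) message("[cherrypop] ", ...)

  # stage 1: data
  log_step("stage seqdata")
  if (!is.null(cfg$input$fixture)) {
    ds <- make_fixture(cfg$input$fixture, seed = stage_seed(cfg$seed, "data"),
                       scale = cfg$input$scale %||% 1)
  } else {
    ds <- read_dataset(cfg$input$fasta, cfg$input$metadata)
  }
  ra <- recode_indels(ds, mode = cfg$indel_mode)
  ht <- collapse_haplotypes(ra, relabel = "by_frequency")
  summ <- summarize_alignment(ra)
  write_haplotype_table(ht, file.path(out, "haplotypes.tsv"))
  write_haplotype_fasta(ht, file.path(out, "haplotypes.fasta"))

  # stage 2: distances
  log_step("stage distances")
  dm_p <- pairwise_differences(ht)
  dm_tn <- suppressWarnings(tn93(ht))
  write_distance_matrix(dm_tn, file.path(out, "tn93.tsv"))

  # stage 3: diversity / neutrality / mismatch per grouping level
  log_step("stage popstats")
  report <- diversity_report(ht, by = cfg$grouping, n_sims = cfg$n_sims,
                             n_boot = cfg$n_boot,
                             seed = stage_seed(cfg$seed, "neutrality"))
  write_diversity_table(report, file.path(out, "diversity.tsv"))

  # stage 4: AMOVA + pairwise Fst
  log_step("stage amova")
  am <- amova(ht, dm_tn, n_perm = cfg$n_perm,
              seed = stage_seed(cfg$seed, "amova"))
  write_amova_table(am, file.path(out, "amova.tsv"))
  fst <- pairwise_fst(ht, dm_tn, n_perm = cfg$n_perm,
                      seed = stage_seed(cfg$seed, "fst"),
                      level = cfg$grouping)
  write_fst_matrix(fst, file.path(out, "fst.tsv"))

  # stage 5: median-joining network
  log_step("stage network")
  net <- median_joining(ht)
  export_network(net, file.path(out, "network.graphml"), "graphml")
  export_network(net, file.path(out, "network_edges.tsv"), "edgelist")
  export_network(net, file.path(out, "network_nodes.tsv"), "nodes")

  # stage 6: ABC (optional)
  abc_res <- NULL
  if (cfg$abc$enabled) {
    log_step("stage abc")
    scen <- demographic_scenarios("three_group")
    chinese <- ht$deme_info$group %in% c("CC", "WC", "RC")
    ht3 <- subset_haplotypes(ht, demes = ht$deme_info$deme[chinese])
    obs <- summary_stats(ht3, level = "group")
    sizes <- table(ht3$samples$group)
    sizes <- stats::setNames(as.integer(sizes), names(sizes))
    rt <- build_reference(scen,
                          n_per_scenario = cfg$abc$n_per_scenario %||% 2000L,
                          sample_sizes = sizes, L = ht$n_base,
                          seed = stage_seed(cfg$seed, "abc"), level = "deme")
    mc <- model_choice(rt, obs, retain = cfg$abc$retain %||% 0.01)
    pe <- estimate_parameters(rt, obs, scenario_name = mc$selected_scenario,
                              retain = cfg$abc$retain %||% 0.01)
    abc_res <- list(model_choice = mc, parameters = pe)
    jsonlite::write_json(
      list(posterior = mc$posterior, selected = mc$selected_scenario,
           method = mc$method, parameters = pe$summary),
      file.path(out, "abc.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }

  manifest <- list(
    package = "cherrypop",
    version = as.character(utils::packageVersion("cherrypop")),
    config = unclass(cfg),
    stage_seeds = lapply(stats::setNames(nm = c("data", "neutrality",
                                                "mismatch", "amova", "fst",
                                                "network", "abc")),
                         function(s) stage_seed(cfg$seed, s)),
    summary = unclass(summ))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, haplotypes = ht, summary = summ,
                 diversity = report, amova = am, fst = fst, network = net,
                 abc = abc_res, manifest = manifest))
}
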