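# One-config orchestration of the full synthetic two-condition analysis:
# simulate -> balance -> compartments -> domains -> loops -> integrate.
# Every effective parameter is echoed into a JSON run manifest along with
# the md5 of every file a stage wrote, so a run is reproducible and
# auditable. Rerunning with an identical config reproduces identical
# outputs byte for byte.

#' Pipeline run configuration
#'
#' Defaults are the analysis thresholds used throughout: compartments at
#' 100 kb with switch delta 1.5, insulation at the native 10 kb with a
#' 100 kb window, loops at q < 0.01 with loose cutoff 0.1, promoter window
#' TSS +/- 2 kb, and DEG thresholds FDR 0.05 / |logFC| 0.58 / stable band
#' 0.38 / logCPM > 0.
#' @param outdir output directory
#' @param seed master seed (drives the simulation and every stochastic
#'   stage)
#' @param stages character vector of stages to run, in dependency order
#' @param sim a [sim_config()]; its seed is overridden by `seed`
#' @param compartment_resolution_bp,delta_threshold compartment stage
#' @param insulation_window_bp,min_prominence domains stage
#' @param loop_min_distance_bp,loop_max_distance_bp,q_call,q_loose loops
#' @param promoter_window_bp,fdr_cutoff,logfc_cutoff,stable_logfc integrate
#' @param pileup_pad_bins,pileup_shifts pile-up geometry
#' @return a validated `RunConfig`
#' @export
run_config <- function(outdir = "loopdelta_run",
                       seed = 1L,
                       stages = c("simulate", "balance", "compartments",
                                  "domains", "loops", "integrate"),
                       sim = sim_config(seed = seed),
                       compartment_resolution_bp = 1e5,
                       delta_threshold = 1.5,
                       insulation_window_bp = 1e5,
                       min_prominence = 0.2,
                       loop_min_distance_bp = 30000,
                       loop_max_distance_bp = 5e6,
                       q_call = 0.01,
                       q_loose = 0.1,
                       promoter_window_bp = 2000,
                       fdr_cutoff = 0.05,
                       logfc_cutoff = 0.58,
                       stable_logfc = 0.38,
                       pileup_pad_bins = 10L,
                       pileup_shifts = 10L) {
  known <- c("simulate", "balance", "compartments", "domains", "loops",
             "integrate")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg <- as.list(environment())
  cfg$known <- NULL
  cfg$bad <- NULL
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a flat key: value text file
#'
#' One `key: value` pair per line, `#` comments allowed. Keys are the
#' [run_config()] arguments; simulation parameters take a `sim.` prefix
#' (e.g. `sim.n_loops_shared: 5`); `stages` is a comma-separated list.
#' Unknown keys are rejected.
#' @param path config file
#' @return a `RunConfig`
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  if (any(vapply(kv, length, 0L) != 3))
    stopf("malformed config line: %s", lines[which(vapply(kv, length, 0L) != 3)[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  parse_val <- function(v) {
    if (v %in% c("true", "TRUE", "True")) return(TRUE)
    if (v %in% c("false", "FALSE", "False")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  sim_args <- list()
  run_args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- parse_val(vals[i])
    if (startsWith(k, "sim.")) {
      sk <- sub("^sim\\.", "", k)
      if (!sk %in% names(formals(sim_config))) stopf("unknown config key: %s", k)
      sim_args[[sk]] <- v
    } else if (k == "stages") {
      run_args$stages <- trimws(strsplit(vals[i], ",")[[1]])
    } else {
      if (!k %in% names(formals(run_config))) stopf("unknown config key: %s", k)
      run_args[[k]] <- v
    }
  }
  if (!is.null(run_args$seed)) sim_args$seed <- run_args$seed
  run_args$sim <- do.call(sim_config, sim_args)
  do.call(run_config, run_args)
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order. A failing stage
#' aborts the run: downstream stages are not attempted, and the manifest
#' records the failure. Returns the manifest (also written as
#' `manifest.json` in `outdir`).
#' @param config a [run_config()]
#' @param quiet suppress progress messages
#' @return the run manifest, invisibly
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[loopdelta] ", fmt), ...))
  manifest <- list(package_version = as.character(utils::packageVersion("loopdelta")),
                   seed = config$seed,
                   parameters = config[!(names(config) %in% c("sim", "stages"))],
                   sim_parameters = unclass(config$sim),
                   stages = list())
  state <- new.env(parent = emptyenv())
  path <- function(...) file.path(config$outdir, paste0(...))

  record <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(
      status = "completed",
      outputs = as.list(tools::md5sum(outputs)))
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
    write_manifest()
    stopf("stage '%s' failed: %s (downstream stages not attempted)",
          stage, conditionMessage(err))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
  }

  stage_fns <- list(
    simulate = function() {
      truth <- simulate_truth(config$sim)
      state$truth <- truth
      state$mat_A <- simulate_contact_matrix(truth, config$sim, "A")
      state$mat_B <- simulate_contact_matrix(truth, config$sim, "B")
      state$genes_de <- simulate_expression_table(truth, config$sim)
      state$peaks <- simulate_peaks(truth, config$sim)
      outs <- character(0)
      for (cond in c("A", "B")) {
        outs <- c(outs, write_contact_matrix(
          state[[paste0("mat_", cond)]],
          path("bins_", cond, ".tsv"), path("matrix_", cond, ".coo.tsv")))
      }
      res <- config$sim$bin_size_bp
      lp <- truth$loops
      write_bedpe(data.frame(chrom1 = truth$chrom, start1 = lp$bin1 * res,
                             end1 = (lp$bin1 + 1) * res, chrom2 = truth$chrom,
                             start2 = lp$bin2 * res, end2 = (lp$bin2 + 1) * res,
                             name = lp$membership, score = lp$fold),
                  path("truth_loops.bedpe"))
      write_genes(state$genes_de, path("genes.tsv"))
      write_narrowpeak(state$peaks, path("peaks.narrowPeak"))
      utils::write.table(
        data.frame(bin = seq_len(truth$n_bins) - 1L,
                   label_A = truth$label_A, label_B = truth$label_B,
                   tad_boundary = (seq_len(truth$n_bins) - 1L) %in% truth$tad_boundaries),
        path("truth_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      record("simulate", c(outs, path("truth_loops.bedpe"), path("genes.tsv"),
                           path("peaks.narrowPeak"), path("truth_labels.tsv")))
    },
    balance = function() {
      for (cond in c("A", "B")) {
        cm <- balance_matrix(state[[paste0("mat_", cond)]])
        state[[paste0("mat_", cond)]] <- cm
        utils::write.table(
          data.frame(bin = seq_len(n_bins(cm)) - 1L, weight = cm$weights),
          path("weights_", cond, ".tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      }
      record("balance", c(path("weights_A.tsv"), path("weights_B.tsv")))
    },
    compartments = function() {
      factor <- as.integer(config$compartment_resolution_bp /
                             config$sim$bin_size_bp)
      evs <- list()
      for (cond in c("A", "B")) {
        cc <- balance_matrix(coarsen_matrix(state[[paste0("mat_", cond)]], factor))
        oe <- observed_over_expected(cc)
        ev <- compute_eigenvector(oe)$ev1
        ref <- peak_coverage(state$peaks, cc$bins)
        evs[[cond]] <- orient_eigenvector(ev, ref)
        state$comp_bins <- cc$bins
        write_bedgraph(data.frame(chrom = cc$bins$chrom, start = cc$bins$start,
                                  end = cc$bins$end, value = evs[[cond]]),
                       path("ev1_", cond, ".bedGraph"))
      }
      sw <- classify_switches(evs$A, evs$B, state$comp_bins,
                              delta_threshold = config$delta_threshold)
      state$switches <- sw
      utils::write.table(sw, path("switches.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("compartments", c(path("ev1_A.bedGraph"), path("ev1_B.bedGraph"),
                               path("switches.tsv")))
    },
    domains = function() {
      outs <- character(0)
      for (cond in c("A", "B")) {
        tr <- insulation_score(state[[paste0("mat_", cond)]],
                               window_bp = config$insulation_window_bp)
        state[[paste0("insul_", cond)]] <- tr
        f <- path("insulation_", cond, ".bedGraph")
        write_bedgraph(data.frame(chrom = tr$chrom, start = tr$start,
                                  end = tr$end, value = tr$score), f)
        outs <- c(outs, f)
      }
      bnd <- call_boundaries(state$insul_A, config$min_prominence)
      tads <- tads_from_boundaries(bnd, state$insul_A)
      state$tads <- tads
      utils::write.table(tads[, c("chrom", "start", "end")],
                         path("tads_A.bed"), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      record("domains", c(outs, path("tads_A.bed")))
    },
    loops = function() {
      lc <- loopcall_config(resolution_bp = config$sim$bin_size_bp,
                            min_distance_bp = config$loop_min_distance_bp,
                            max_distance_bp = config$loop_max_distance_bp,
                            q_call = config$q_call, q_loose = config$q_loose)
      tabs <- list()
      for (cond in c("A", "B")) {
        cm <- state[[paste0("mat_", cond)]]
        prior <- fit_distance_prior(cm, lc)
        called <- call_loops(loop_pvalues(cm, prior), cm, prior, lc$q_call)
        tabs[[cond]] <- called$table
      }
      diff <- classify_differential(tabs$A, tabs$B, lc)
      state$diff_loops <- diff
      utils::write.table(diff, path("loops_differential.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res <- config$sim$bin_size_bp
      write_bedpe(data.frame(chrom1 = "chr1", start1 = diff$bin1 * res,
                             end1 = (diff$bin1 + 1) * res, chrom2 = "chr1",
                             start2 = diff$bin2 * res,
                             end2 = (diff$bin2 + 1) * res,
                             name = diff$diff_class, score = diff$score_A),
                  path("loops_differential.bedpe"))
      record("loops", c(path("loops_differential.tsv"),
                        path("loops_differential.bedpe")))
    },
    integrate = function() {
      genes <- classify_genes(state$genes_de, fdr = config$fdr_cutoff,
                              logfc = config$logfc_cutoff,
                              stable_logfc = config$stable_logfc)
      po <- promoter_peak_overlap(genes, state$peaks,
                                  window_bp = config$promoter_window_bp)
      genes <- po$genes
      diff <- state$diff_loops
      ann <- annotate_promoter_loops(diff, genes,
                                     window_bp = config$promoter_window_bp,
                                     resolution_bp = config$sim$bin_size_bp)
      strat <- stratified_loop_scores(ann, diff, genes, score_col = "score_A")
      utils::write.table(ann, path("promoter_loops.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(strat$summary, path("stratified_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      occ <- data.frame(expr_class = names(po$occupancy),
                        occupancy = as.numeric(po$occupancy))
      utils::write.table(occ, path("promoter_occupancy.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      loci <- diff[diff$diff_class %in% c("common", "A_specific"),
                   c("bin1", "bin2"), drop = FALSE]
      if (nrow(loci)) {
        pu <- pileup_dots(state$mat_A, utils::head(loci, 200),
                          pad_bins = config$pileup_pad_bins,
                          n_shifts = config$pileup_shifts,
                          seed = derive_seed(config$seed, 77L))
        utils::write.table(round(pu$map, 6), path("pileup_A.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE, col.names = FALSE)
      }
      record("integrate", c(path("promoter_loops.tsv"),
                            path("stratified_scores.tsv"),
                            path("promoter_occupancy.tsv"),
                            if (nrow(loci)) path("pileup_A.tsv")))
    })

  order_known <- c("simulate", "balance", "compartments", "domains", "loops",
                   "integrate")
  to_run <- order_known[order_known %in% config$stages]
  for (stage in to_run) {
    say("stage %s ...", stage)
    tryCatch(stage_fns[[stage]](), error = function(e) fail(stage, e))
    say("stage %s done", stage)
  }
  write_manifest()
  invisible(manifest)
}
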