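study_rna_ids <- function(n = 10) {
  ids <- c("TP53", "HRAS", "MYC", "BCL2", "PWRN1", "SOX2OT", "OCC1",
           "IGF2RNC", "lncRBM26", "DLEU1")
  if (n <= length(ids)) ids[seq_len(n)] else
    c(ids, sprintf("RNA%02d", seq_len(n - length(ids)) + length(ids)))
}

#' Simulation configuration for synthetic array scans
#'
#' Describes a full screen: the slide geometry, the noise model and the
#' planted ground truth. Defaults emulate the screen the package targets:
#' 9125 non-control proteins spotted in duplicate across 48 sub-array blocks
#' (22 x 22 spots each, duplicates adjacent), 10 RNA loci probed on both
#' strands (20 scans), 137 planted sense-specific interactions with folds
#' between 3 and 8, and 28 "common binder" proteins attached non-specifically
#' to both strands of most loci. Background intensities are log-normal around
#' 500 AU; non-binder ratios are log-normal around 1 with sd 0.1 on the log
#' scale; intensities are rounded to integers as a scanner reports them.
#'
#' When `planted` / `shared_nonspecific` are `NULL` they are generated
#' reproducibly from `seed`; pass explicit tibbles (or zero-row tibbles) to
#' control the truth directly.
#'
#' @param n_proteins Number of non-control proteins.
#' @param n_blocks Number of printing blocks.
#' @param controls_per_block Positive-control features per block (also
#'   spotted in duplicate).
#' @param n_rnas Number of RNA loci (each simulated on both strands).
#' @param rna_ids Locus identifiers.
#' @param background_log_mean,background_log_sd Log-normal parameters of the
#'   per-protein background level (AU).
#' @param nonspecific_log_sd SD of the log signal/background ratio of
#'   non-binders (and around the planted fold for binders).
#' @param duplicate_log_sd SD of the spot-to-spot log perturbation of the
#'   background level between duplicates.
#' @param control_f635 Fixed bright foreground of control spots.
#' @param planted Tibble `protein_id`, `rna_id`, `strand`, `fold` of planted
#'   interactions (`fold` > 1), or `NULL` to generate `n_planted` of them.
#' @param shared_nonspecific Tibble `protein_id`, `rna_id`, `fold` applied to
#'   both strands of the locus, or `NULL` to generate.
#' @param n_planted,planted_fold_range Number and fold range of generated
#'   sense-specific interactions.
#' @param n_shared,shared_fold_range,shared_loci_range Number of generated
#'   common binders, their fold range, and the range of loci count each binds.
#' @param seed Integer master seed; every scan derives its own substream.
#' @return A `sim_config` list.
#' @seealso [simulate_scan()], [simulate_experiment()]
#' @export
sim_config <- function(n_proteins = 9125, n_blocks = 48,
                       controls_per_block = 2, n_rnas = 10,
                       rna_ids = study_rna_ids(n_rnas),
                       background_log_mean = log(500),
                       background_log_sd = 0.4,
                       nonspecific_log_sd = 0.1,
                       duplicate_log_sd = 0.05,
                       control_f635 = 60000,
                       planted = NULL, shared_nonspecific = NULL,
                       n_planted = 137, planted_fold_range = c(3, 8),
                       n_shared = 28, shared_fold_range = c(3, 6),
                       shared_loci_range = c(7, 10),
                       seed = 1L) {
  check_number(n_proteins, "n_proteins", min = 2)
  check_number(n_blocks, "n_blocks", min = 1)
  check_number(n_rnas, "n_rnas", min = 1)
  check_number(nonspecific_log_sd, "nonspecific_log_sd", min = 0)
  check_number(duplicate_log_sd, "duplicate_log_sd", min = 0)
  check_number(background_log_sd, "background_log_sd", min = 0)
  if (length(rna_ids) != n_rnas) stop_param("`rna_ids` must have length `n_rnas`.")
  cfg <- structure(list(
    n_proteins = as.integer(n_proteins), n_blocks = as.integer(n_blocks),
    controls_per_block = as.integer(controls_per_block),
    n_rnas = as.integer(n_rnas), rna_ids = as.character(rna_ids),
    background_log_mean = background_log_mean,
    background_log_sd = background_log_sd,
    nonspecific_log_sd = nonspecific_log_sd,
    duplicate_log_sd = duplicate_log_sd,
    control_f635 = control_f635,
    planted = planted, shared_nonspecific = shared_nonspecific,
    n_planted = as.integer(n_planted),
    planted_fold_range = planted_fold_range,
    n_shared = as.integer(n_shared),
    shared_fold_range = shared_fold_range,
    shared_loci_range = as.integer(shared_loci_range),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_truth(cfg)
  cfg
}

sim_protein_ids <- function(cfg) sprintf("PROT_%05d", seq_len(cfg$n_proteins))

validate_truth <- function(cfg) {
  ids <- NULL
  for (nm in c("planted", "shared_nonspecific")) {
    tr <- cfg[[nm]]
    if (is.null(tr)) next
    if (!inherits(tr, "data.frame")) stop_param(sprintf("`%s` must be a data frame.", nm))
    if (nrow(tr) == 0) next
    if (any(tr$fold <= 1)) stop_param(sprintf("`%s` folds must be > 1.", nm))
    if (is.null(ids)) ids <- sim_protein_ids(cfg)
    bad <- setdiff(unique(tr$protein_id), ids)
    if (length(bad) > 0) {
      stop_param(sprintf("`%s` protein(s) outside the simulated array: %s",
                         nm, compact_ids(bad)))
    }
    if (!all(tr$rna_id %in% cfg$rna_ids)) {
      stop_param(sprintf("`%s` references unknown rna_id(s).", nm))
    }
    if (nm == "planted" && !all(tr$strand %in% c("sense", "antisense"))) {
      stop_param("`planted` strand must be 'sense' or 'antisense'.")
    }
  }
  invisible(cfg)
}

# Fill in generated truth tables where the config leaves them NULL.
# Deterministic in cfg$seed; planted and shared protein pools are disjoint.
materialize_truth <- function(cfg) {
  ids <- sim_protein_ids(cfg)
  if (is.null(cfg$shared_nonspecific)) {
    set.seed(derive_seed(cfg$seed, "shared"))
    shared_prot <- sample(ids, cfg$n_shared)
    cfg$shared_nonspecific <- bind_rows(lapply(shared_prot, function(p) {
      k <- sample(seq(cfg$shared_loci_range[1],
                      min(cfg$shared_loci_range[2], cfg$n_rnas)), 1)
      tibble(protein_id = p,
             rna_id = sample(cfg$rna_ids, k),
             fold = runif(k, cfg$shared_fold_range[1], cfg$shared_fold_range[2]))
    }))
  }
  if (is.null(cfg$planted)) {
    set.seed(derive_seed(cfg$seed, "planted"))
    pool <- setdiff(ids, unique(cfg$shared_nonspecific$protein_id))
    # some proteins bind several RNAs: draw pairs until n_planted unique ones
    pairs <- tibble(protein_id = character(0), rna_id = character(0))
    while (nrow(pairs) < cfg$n_planted) {
      need <- cfg$n_planted - nrow(pairs)
      extra <- tibble(
        protein_id = sample(pool, need, replace = TRUE),
        rna_id = sample(cfg$rna_ids, need, replace = TRUE)
      )
      pairs <- distinct(bind_rows(pairs, extra))
    }
    cfg$planted <- mutate(pairs,
      strand = "sense",
      fold = runif(nrow(pairs), cfg$planted_fold_range[1], cfg$planted_fold_range[2])
    )
  }
  validate_truth(cfg)
  cfg
}

# Deterministic slide layout: proteins fill blocks sequentially after the
# control features; duplicates sit in adjacent columns of a 22-wide block.
sim_layout <- function(cfg) {
  ids <- sim_protein_ids(cfg)
  n_ctrl <- cfg$n_blocks * cfg$controls_per_block
  feat_ids <- c(ids, if (n_ctrl > 0) sprintf("CTRL_POS_%03d", seq_len(n_ctrl)))
  feat_names <- c(sprintf("protein %d", seq_len(cfg$n_proteins)),
                  rep("Positive Control", n_ctrl))
  is_ctrl <- c(rep(FALSE, cfg$n_proteins), rep(TRUE, n_ctrl))
  # interleave controls first within each block, then proteins
  per_block <- ceiling(cfg$n_proteins / cfg$n_blocks) + cfg$controls_per_block
  if (per_block > 242) stop_param("layout overflow: too many features per block.")
  block_of <- integer(length(feat_ids))
  slot_of <- integer(length(feat_ids))
  # controls: first controls_per_block slots of each block
  if (n_ctrl > 0) {
    ci <- cfg$n_proteins + seq_len(n_ctrl)
    block_of[ci] <- rep(seq_len(cfg$n_blocks), each = cfg$controls_per_block)
    slot_of[ci] <- rep(seq_len(cfg$controls_per_block), times = cfg$n_blocks)
  }
  # proteins: remaining slots, filled block by block
  pi <- seq_len(cfg$n_proteins)
  per_block_prot <- per_block - cfg$controls_per_block
  block_of[pi] <- (pi - 1) %/% per_block_prot + 1L
  slot_of[pi] <- (pi - 1) %% per_block_prot + 1L + cfg$controls_per_block
  # slot -> (row, col pair): 11 duplicate pairs per 22-column row
  row <- (slot_of - 1) %/% 11 + 1L
  colpair <- (slot_of - 1) %% 11
  tibble(
    feature = seq_along(feat_ids),
    protein_id = feat_ids, protein_name = feat_names, is_control = is_ctrl,
    block = block_of, row = row,
    col1 = 2L * colpair + 1L, col2 = 2L * colpair + 2L
  )
}

# fold multipliers for one (rna, strand): planted strand-specific + shared both-strand
scan_folds <- function(cfg, rna_id, strand) {
  folds <- c()
  pl <- cfg$planted
  if (!is.null(pl) && nrow(pl) > 0) {
    pl <- pl[pl$rna_id == rna_id & pl$strand == strand, , drop = FALSE]
    folds <- setNames(pl$fold, pl$protein_id)
  }
  sh <- cfg$shared_nonspecific
  if (!is.null(sh) && nrow(sh) > 0) {
    sh <- sh[sh$rna_id == rna_id, , drop = FALSE]
    folds <- c(folds, setNames(sh$fold, sh$protein_id))
  }
  folds
}

#' Simulate one array scan
#'
#' Draws a full slide for one RNA incubation under the configured noise
#' model: each protein gets a log-normal background level, each duplicate
#' spot perturbs it independently, and the foreground is the spot background
#' times a log-normal ratio centered on the planted fold (1 for non-binders).
#' Control spots get a fixed bright foreground. Intensities are rounded to
#' integers. Output is deterministic given `(cfg$seed, rna_id, strand,
#' replicate)`.
#'
#' @param cfg A [sim_config()].
#' @param rna_id One of `cfg$rna_ids`.
#' @param strand `"sense"` or `"antisense"`.
#' @param replicate Replicate tag; a different tag reuses the same truth with
#'   fresh noise (for technical-replicate simulations).
#' @return List with `scan` (an [array_scan()]) and `expected_hits` (planted
#'   or shared proteins for this scan whose fold is at least 2.5, the default
#'   fold threshold).
#' @export
simulate_scan <- function(cfg, rna_id, strand, replicate = 1L) {
  if (!inherits(cfg, "sim_config")) stop_input("`cfg` must be a sim_config.")
  if (!rna_id %in% cfg$rna_ids) stop_input(sprintf("unknown rna_id '%s'.", rna_id))
  if (!strand %in% c("sense", "antisense")) {
    stop_input('`strand` must be "sense" or "antisense".')
  }
  cfg <- materialize_truth(cfg)
  layout <- sim_layout(cfg)
  set.seed(derive_seed(cfg$seed, paste(rna_id, strand, replicate, sep = "|")))

  n_feat <- nrow(layout)
  fold <- rep(1, n_feat)
  planted_folds <- scan_folds(cfg, rna_id, strand)
  if (length(planted_folds) > 0) {
    fold[match(names(planted_folds), layout$protein_id)] <- planted_folds
  }

  b_level <- rlnorm(n_feat, cfg$background_log_mean, cfg$background_log_sd)
  spot_b <- function() b_level * rlnorm(n_feat, 0, cfg$duplicate_log_sd)
  spot_r <- function() rlnorm(n_feat, log(fold), cfg$nonspecific_log_sd)
  b1 <- spot_b(); b2 <- spot_b()
  f1 <- b1 * spot_r(); f2 <- b2 * spot_r()
  f1[layout$is_control] <- cfg$control_f635
  f2[layout$is_control] <- cfg$control_f635

  spots <- tibble(
    block = rep(layout$block, 2),
    row = rep(layout$row, 2),
    column = c(layout$col1, layout$col2),
    protein_id = rep(layout$protein_id, 2),
    protein_name = rep(layout$protein_name, 2),
    f635 = round(c(f1, f2)),
    b635 = round(c(b1, b2)),
    flag = 0L,
    is_control = rep(layout$is_control, 2)
  )
  spots <- arrange(spots, .data$block, .data$row, .data$column)
  scan <- array_scan(
    spots,
    scan_id = paste(rna_id, strand,
                    if (replicate != 1L) paste0("rep", replicate) else NULL,
                    sep = "_"),
    rna_id = rna_id, strand = strand, n_blocks = cfg$n_blocks
  )
  expected <- as.character(sort(names(planted_folds)[planted_folds >= 2.5]))
  list(scan = scan, expected_hits = expected)
}

#' Simulate a full screen with ground truth
#'
#' One sense and one antisense scan per locus. Shared non-specific folds are
#' applied to both strands, so antisense subtraction removes them; the truth
#' records the planted sense-specific interactions that the pipeline should
#' recover.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_experiment` list: `scans` (named list of [array_scan()]s,
#'   `"<rna>_<strand>"`), `truth` (list with `interactions` — tibble
#'   `protein_id`, `rna_id`, `fold` of planted sense-specific pairs —,
#'   `shared` and per-scan `expected_hits`), and the materialized `config`.
#' @export
simulate_experiment <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_input("`cfg` must be a sim_config.")
  cfg <- materialize_truth(cfg)
  scans <- list()
  expected <- list()
  for (rna in cfg$rna_ids) {
    for (strand in c("sense", "antisense")) {
      sim <- simulate_scan(cfg, rna, strand)
      key <- paste(rna, strand, sep = "_")
      scans[[key]] <- sim$scan
      expected[[key]] <- sim$expected_hits
    }
  }
  planted <- cfg$planted
  interactions <- if (is.null(planted) || nrow(planted) == 0) {
    tibble(protein_id = character(0), rna_id = character(0), fold = numeric(0))
  } else {
    sense <- planted[planted$strand == "sense", , drop = FALSE]
    anti_keys <- with(planted[planted$strand == "antisense", , drop = FALSE],
                      paste(protein_id, rna_id))
    sense <- sense[!paste(sense$protein_id, sense$rna_id) %in% anti_keys, , drop = FALSE]
    arrange(as_tibble(sense[c("protein_id", "rna_id", "fold")]),
            .data$rna_id, .data$protein_id)
  }
  structure(
    list(scans = scans,
         truth = list(interactions = interactions,
                      shared = cfg$shared_nonspecific,
                      expected_hits = expected),
         config = cfg),
    class = "sim_experiment"
  )
}

#' Write a simulated experiment to disk
#'
#' Emits one GPR file per scan plus a `truth.tsv` of the planted
#' sense-specific interactions, and returns a manifest tibble suitable for
#' [run_pipeline()].
#'
#' @param experiment A `sim_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Manifest tibble with `rna_id`, `strand`, `path`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  if (!inherits(experiment, "sim_experiment")) {
    stop_input("`experiment` must come from simulate_experiment().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- bind_rows(lapply(experiment$scans, function(scan) {
    path <- file.path(dir, paste0(scan$scan_id, ".gpr"))
    write_gpr(scan, path)
    tibble(rna_id = scan$rna_id, strand = scan$strand, path = path)
  }))
  readr::write_tsv(experiment$truth$interactions, file.path(dir, "truth.tsv"))
  invisible(manifest)
}
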