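#' Assay design parameters for a PEG-precipitation run
#'
#' Collects all titration parameters for one automated PEG-precipitation
#' assay: the final well volume, the target protein concentration and its
#' stock, the available PEG stock concentrations, the final PEG
#' concentrations to titrate, and replication. The defaults describe the
#' standard screening run: 10 uL wells at 1 mg/mL protein from a 3 mg/mL
#' stock, PEG stocks at 15/30/50 % w/v, twelve PEG concentrations from 0 to
#' the maximum achievable 33.33 % w/v, two replicates and one blank per
#' concentration, and a 0.33 uL minimum transfer volume.
#'
#' @param final_well_volume final volume per well, uL.
#' @param final_protein_conc target protein concentration in the well, mg/mL.
#' @param protein_stock_conc protein stock concentration, mg/mL.
#' @param peg_stock_concs available PEG stock concentrations, % w/v,
#'   ascending.
#' @param peg_targets final PEG concentrations to titrate, % w/v, strictly
#'   increasing, non-negative.
#' @param replicates_per_conc sample wells per PEG concentration.
#' @param blanks_per_conc blank (PEG + buffer, no protein) wells per
#'   concentration.
#' @param min_transfer_volume smallest volume the liquid handler transfers
#'   accurately, uL.
#' @param protein_id label recorded in layouts and worklists.
#' @return an object of class `"design_config"`.
#' @examples
#' cfg <- design_config()
#' max_achievable_peg(cfg)
#' @export
design_config <- function(final_well_volume = 10,
                          final_protein_conc = 1,
                          protein_stock_conc = 3,
                          peg_stock_concs = c(15, 30, 50),
                          peg_targets = c(seq(0, 30, by = 3), 100 / 3),
                          replicates_per_conc = 2L,
                          blanks_per_conc = 1L,
                          min_transfer_volume = 0.33,
                          protein_id = "protein") {
  cfg <- list(
    final_well_volume = final_well_volume,
    final_protein_conc = final_protein_conc,
    protein_stock_conc = protein_stock_conc,
    peg_stock_concs = sort(peg_stock_concs),
    peg_targets = peg_targets,
    replicates_per_conc = as.integer(replicates_per_conc),
    blanks_per_conc = as.integer(blanks_per_conc),
    min_transfer_volume = min_transfer_volume,
    protein_id = protein_id
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

validate_design_config <- function(cfg) {
  stopifnot(
    cfg$final_well_volume > 0,
    cfg$final_protein_conc >= 0,
    cfg$final_protein_conc <= cfg$protein_stock_conc,
    all(cfg$peg_stock_concs > 0),
    all(cfg$peg_targets >= 0),
    cfg$replicates_per_conc >= 1L,
    cfg$blanks_per_conc >= 0L,
    cfg$min_transfer_volume >= 0
  )
  if (is.unsorted(cfg$peg_targets, strictly = TRUE)) {
    stop("peg_targets must be strictly increasing")
  }
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("PEG precipitation assay design\n")
  cat(sprintf("  final well volume : %g uL\n", x$final_well_volume))
  cat(sprintf("  protein           : %g mg/mL final from %g mg/mL stock (%s)\n",
              x$final_protein_conc, x$protein_stock_conc, x$protein_id))
  cat(sprintf("  PEG stocks        : %s %% w/v\n",
              paste(x$peg_stock_concs, collapse = ", ")))
  cat(sprintf("  PEG targets       : %s %% w/v\n",
              paste(signif(x$peg_targets, 4), collapse = ", ")))
  cat(sprintf("  replicates/blanks : %d / %d per concentration\n",
              x$replicates_per_conc, x$blanks_per_conc))
  cat(sprintf("  max achievable PEG: %.2f %% w/v\n", max_achievable_peg(x)))
  invisible(x)
}

#' Maximum achievable final PEG concentration
#'
#' The volume budget for PEG in a well is everything not taken by the
#' protein stock. With the strongest PEG stock filling that whole budget the
#' final concentration is `max(stock) * (V - v_protein) / V`, where
#' `v_protein = final_protein_conc * V / protein_stock_conc`. At the default
#' 3 mg/mL protein stock this gives 33.33 % w/v; concentrating the protein
#' stock to 10 mg/mL (1 uL of protein per 10 uL well) raises it to 45 % w/v.
#'
#' @param config a [design_config()].
#' @return maximum final PEG concentration, % w/v.
#' @examples
#' max_achievable_peg(design_config())                         # 33.33
#' max_achievable_peg(design_config(protein_stock_conc = 10))  # 45
#' @export
max_achievable_peg <- function(config) {
  validate_design_config(config)
  v <- config$final_well_volume
  v_protein <- protein_volume(config)
  max(config$peg_stock_concs) * (v - v_protein) / v
}

protein_volume <- function(config) {
  if (config$final_protein_conc == 0) return(0)
  config$final_protein_conc * config$final_well_volume / config$protein_stock_conc
}

# Pick the PEG stock for one target: the lowest stock concentration whose
# required volume fits the PEG+buffer budget, is >= min_transfer_volume, and
# leaves a buffer remainder that is either zero or itself pipettable. Lower
# stocks need larger volumes, which pipette more accurately in viscous PEG.
choose_stock <- function(target, budget, config, tol = 1e-9) {
  if (target == 0) return(list(stock = NA_real_, v_peg = 0))
  for (stock in config$peg_stock_concs) {
    v_peg <- target * config$final_well_volume / stock
    if (v_peg > budget + tol) next
    if (v_peg < config$min_transfer_volume - tol) next
    v_buffer <- budget - v_peg
    if (v_buffer > tol && v_buffer < config$min_transfer_volume - tol) next
    return(list(stock = stock, v_peg = v_peg))
  }
  stop(sprintf(
    "PEG target %.4g%% w/v is not achievable: no stock gives a volume within [%g uL, %.4g uL budget]",
    target, config$min_transfer_volume, budget))
}

#' Compute per-well titration recipes
#'
#' Expands a [design_config()] into one recipe per well: sample wells for
#' every PEG target x replicate, followed by blank wells (same PEG and
#' buffer recipe with the protein volume replaced by buffer). Wells are
#' assigned row-major on a 384-well plate, replicates adjacent and blanks
#' after the replicates of each concentration. For each target the lowest
#' PEG stock that satisfies both the volume budget and the minimum transfer
#' volume is used.
#'
#' @param config a [design_config()].
#' @return a data frame of class `"well_plan"` with columns `well`, `role`
#'   (`"sample"`/`"blank"`), `peg_pct`, `peg_stock`, `v_peg`, `v_buffer`,
#'   `v_protein` (uL) and `replicate`; the design is kept in
#'   `attr(, "config")`.
#' @examples
#' plan <- plan_assay(design_config())
#' nrow(plan)  # 36 wells: (2 replicates + 1 blank) x 12 concentrations
#' @export
plan_assay <- function(config = design_config()) {
  validate_design_config(config)
  v <- config$final_well_volume
  v_protein <- protein_volume(config)
  if (v_protein > 0 && v_protein < config$min_transfer_volume) {
    stop("protein volume ", signif(v_protein, 4), " uL is below the minimum transfer volume")
  }
  budget <- v - v_protein

  rows <- list()
  for (target in config$peg_targets) {
    sel <- choose_stock(target, budget, config)
    v_buffer <- budget - sel$v_peg
    if (abs(v_buffer) < 1e-9) v_buffer <- 0
    for (r in seq_len(config$replicates_per_conc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        role = "sample", peg_pct = target, peg_stock = sel$stock,
        v_peg = sel$v_peg, v_buffer = v_buffer, v_protein = v_protein,
        replicate = r, stringsAsFactors = FALSE)
    }
    for (b in seq_len(config$blanks_per_conc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        role = "blank", peg_pct = target, peg_stock = sel$stock,
        v_peg = sel$v_peg, v_buffer = v_buffer + v_protein, v_protein = 0,
        replicate = b, stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, rows)
  plan <- cbind(well = well_ids(nrow(plan)), plan, stringsAsFactors = FALSE)
  plan$protein_id <- config$protein_id
  attr(plan, "config") <- config
  class(plan) <- c("well_plan", "data.frame")
  plan
}

#' Summarize reagent consumption for a planned run
#'
#' @param plan a [plan_assay()] result (may be empty).
#' @param config the matching [design_config()]; taken from the plan when
#'   omitted.
#' @return list of class `"consumables"`: `total_protein_volume` (uL),
#'   `total_protein_mass` (ug), `peg_volumes` (uL, named by stock % w/v),
#'   `total_buffer` (uL), `n_wells`.
#' @examples
#' summarize_consumables(plan_assay(design_config()))
#' # 80 uL protein stock, 240 ug protein for the standard 12 x 2 run
#' @export
summarize_consumables <- function(plan, config = attr(plan, "config")) {
  if (is.null(plan) || nrow(plan) == 0L) {
    out <- list(total_protein_volume = 0, total_protein_mass = 0,
                peg_volumes = numeric(0), total_buffer = 0, n_wells = 0L)
    class(out) <- "consumables"
    return(out)
  }
  vol_protein <- sum(plan$v_protein)
  peg_volumes <- tapply(plan$v_peg[plan$v_peg > 0], plan$peg_stock[plan$v_peg > 0], sum)
  out <- list(
    total_protein_volume = vol_protein,
    total_protein_mass = vol_protein * config$protein_stock_conc,
    peg_volumes = if (length(peg_volumes)) c(peg_volumes) else numeric(0),
    total_buffer = sum(plan$v_buffer),
    n_wells = nrow(plan)
  )
  class(out) <- "consumables"
  out
}

#' @export
print.consumables <- function(x, ...) {
  cat("Consumables for", x$n_wells, "wells\n")
  cat(sprintf("  protein stock : %.3f uL (%.1f ug protein)\n",
              x$total_protein_volume, x$total_protein_mass))
  for (s in names(x$peg_volumes)) {
    cat(sprintf("  PEG %s%% stock : %.3f uL\n", s, x$peg_volumes[[s]]))
  }
  cat(sprintf("  buffer        : %.3f uL\n", x$total_buffer))
  invisible(x)
}

#' Plan the supernatant transfer into the measurement plate
#'
#' After centrifugation the supernatant of each assay well is transferred
#' into a UV-transparent plate prefilled with buffer. To avoid disturbing
#' the pellet the robot takes a small volume twice from each well (defaults:
#' 3 uL twice, i.e. 6 uL out of 10), which also doubles the number of
#' technical replicates: two sample replicates per concentration become four
#' measurement wells. Destination wells are assigned deterministically in
#' row-major order.
#'
#' @param plan a [plan_assay()] result.
#' @param v_per_transfer volume per aspiration, uL.
#' @param n_transfers transfers per source well; the total removed must
#'   leave at least 2 uL headroom in the source well for evaporation.
#' @param prefill_volume buffer prefilled in each destination well, uL.
#' @param dest_nrow,dest_ncol destination plate geometry.
#' @return data frame of class `"transfer_plan"`, one row per transfer:
#'   `source_well`, `dest_well`, `volume_ul`, `transfer`, plus the source
#'   annotation (`role`, `peg_pct`, `replicate`, `protein_id`).
#' @export
plan_supernatant_transfer <- function(plan, v_per_transfer = 3, n_transfers = 2L,
                                      prefill_volume = 10,
                                      dest_nrow = 16L, dest_ncol = 24L) {
  config <- attr(plan, "config")
  v <- config$final_well_volume
  if (n_transfers * v_per_transfer > v - 2) {
    stop("requested transfers remove ", n_transfers * v_per_transfer,
         " uL but only ", v - 2, " uL is available after evaporation headroom")
  }
  n_dest <- nrow(plan) * n_transfers
  if (n_transfers == 0L || nrow(plan) == 0L) {
    out <- data.frame(source_well = character(0), dest_well = character(0),
                      volume_ul = numeric(0), transfer = integer(0),
                      role = character(0), peg_pct = numeric(0),
                      replicate = integer(0), protein_id = character(0),
                      stringsAsFactors = FALSE)
  } else {
    if (n_dest > dest_nrow * dest_ncol) {
      stop("destination plate capacity exceeded: need ", n_dest, " wells")
    }
    idx <- rep(seq_len(nrow(plan)), each = n_transfers)
    out <- data.frame(
      source_well = plan$well[idx],
      dest_well = well_ids(n_dest, dest_nrow, dest_ncol),
      volume_ul = v_per_transfer,
      transfer = rep(seq_len(n_transfers), times = nrow(plan)),
      role = plan$role[idx],
      peg_pct = plan$peg_pct[idx],
      replicate = plan$replicate[idx],
      protein_id = plan$protein_id[idx],
      stringsAsFactors = FALSE)
  }
  attr(out, "v_per_transfer") <- v_per_transfer
  attr(out, "n_transfers") <- as.integer(n_transfers)
  attr(out, "prefill_volume") <- prefill_volume
  attr(out, "config") <- config
  class(out) <- c("transfer_plan", "data.frame")
  out
}

#' Write a machine-readable worklist
#'
#' Serializes a plan into a delimited worklist, one row per liquid transfer,
#' with columns `step,source_labware,source_well,dest_labware,dest_well,
#' volume_ul,reagent`. For a preparation plan the rows are ordered PEG
#' transfers first, then buffer, then protein (protein last so incubation
#' starts at a well-defined time); zero-volume transfers are omitted.
#' Volumes are written at 0.001 uL precision.
#'
#' @param plan a `"well_plan"` or `"transfer_plan"`.
#' @param path output CSV path.
#' @return the worklist data frame, invisibly.
#' @export
emit_worklist <- function(plan, path) UseMethod("emit_worklist")

#' @export
emit_worklist.well_plan <- function(plan, path) {
  rows <- list()
  add <- function(src_lab, src, dest, vol, reagent) {
    keep <- vol > 0
    if (!any(keep)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      source_labware = src_lab[keep], source_well = src[keep],
      dest_labware = "assay_plate", dest_well = dest[keep],
      volume_ul = vol[keep], reagent = reagent[keep], stringsAsFactors = FALSE)
  }
  stock_lab <- ifelse(is.na(plan$peg_stock), "",
                      paste0("peg_stock_", plan$peg_stock))
  add(stock_lab, rep("A1", nrow(plan)), plan$well, plan$v_peg,
      ifelse(is.na(plan$peg_stock), "", paste0("PEG", plan$peg_stock)))
  add(rep("buffer_reservoir", nrow(plan)), rep("A1", nrow(plan)), plan$well,
      plan$v_buffer, rep("buffer", nrow(plan)))
  add(rep("protein_stock", nrow(plan)), rep("A1", nrow(plan)), plan$well,
      plan$v_protein, rep(plan$protein_id, nrow(plan)))
  wl <- do.call(rbind, rows)
  wl <- cbind(step = seq_len(nrow(wl)), wl)
  write_worklist_csv(wl, path)
}

#' @export
emit_worklist.transfer_plan <- function(plan, path) {
  keep <- plan$volume_ul > 0
  wl <- data.frame(
    step = seq_len(sum(keep)),
    source_labware = "assay_plate", source_well = plan$source_well[keep],
    dest_labware = "measurement_plate", dest_well = plan$dest_well[keep],
    volume_ul = plan$volume_ul[keep], reagent = "supernatant",
    stringsAsFactors = FALSE)
  write_worklist_csv(wl, path)
}

write_worklist_csv <- function(wl, path) {
  out <- wl
  out$volume_ul <- fmt_vol(out$volume_ul)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(wl)
}

#' Read back a worklist written by [emit_worklist()]
#' @param path worklist CSV path.
#' @return data frame with the worklist columns; `volume_ul` numeric.
#' @export
read_worklist <- function(path) {
  wl <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("step", "source_labware", "source_well", "dest_labware",
              "dest_well", "volume_ul", "reagent")
  if (!all(needed %in% names(wl))) stop("not a pegsolve worklist: ", path)
  wl$volume_ul <- as.numeric(wl$volume_ul)
  wl
}

#' Write / read the plate layout table
#'
#' The layout maps wells to their role in the assay and is the join key
#' between planned recipes and measured spectra. Columns:
#' `well,role,peg_pct,replicate,protein_id`.
#'
#' @param plan a `"well_plan"`, `"transfer_plan"` or a data frame already in
#'   layout shape.
#' @param path CSV path.
#' @export
write_layout <- function(plan, path) {
  lay <- as_layout(plan)
  utils::write.csv(lay, path, row.names = FALSE, quote = FALSE)
  invisible(lay)
}

as_layout <- function(plan) {
  if (inherits(plan, "transfer_plan")) {
    data.frame(well = plan$dest_well, role = plan$role, peg_pct = plan$peg_pct,
               replicate = plan$replicate, protein_id = plan$protein_id,
               stringsAsFactors = FALSE)
  } else if (all(c("well", "role", "peg_pct", "replicate") %in% names(plan))) {
    data.frame(well = plan$well, role = plan$role, peg_pct = plan$peg_pct,
               replicate = plan$replicate,
               protein_id = plan$protein_id %||% "protein",
               stringsAsFactors = FALSE)
  } else {
    stop("cannot derive a layout from this object")
  }
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("well", "role", "peg_pct", "replicate")
  if (!all(needed %in% names(lay))) {
    stop("layout file must have columns well,role,peg_pct,replicate: ", path)
  }
  if (is.null(lay$protein_id)) lay$protein_id <- "protein"
  lay
}
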