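#' Region-of-interest table for the 90-node source parcellation
#'
#' Returns the 90 Harvard-Oxford-style regions (45 bilateral pairs) used
#' throughout the pipeline, with their baseline anatomical community
#' (frontal, sensorimotor, temporal, occipital, subcortical, parietal) and,
#' where applicable, their functional-network membership (central executive
#' network CEN, salience network SN, default mode network DMN).
#'
#' The full parcellation transcription contains 56 bilateral pairs; the
#' default 90-ROI table applies a deterministic reduction — the lateral
#' ventricle (not a neural source) and ten fine gyrus-subdivision pairs
#' (STGa, MTGa, MTGto, ITGa, ITGto, TFCa, PP, LOi, PGa, SMGa) are dropped,
#' keeping one representative division per gyrus and every functional-network
#' member. Set `full = TRUE` for the complete 112-label table.
#'
#' @param full Return all 56 bilateral pairs instead of the reduced 45.
#' @return A data.frame with columns `roi` (e.g. "SPL.L"), `abbrev`,
#'   `hemisphere`, `community` (integer 1-6), `community_name`, `network`
#'   (one of "CEN", "SN", "DMN" or NA).
#' @export
roi_table <- function(full = FALSE) {
  # abbrev -> baseline anatomical community
  comm <- list(
    frontal      = c("FP", "SFG", "MFG", "IFGt", "IFGo", "FMC", "SC", "FO", "FOC"),
    sensorimotor = c("PrC", "PoC", "SMA", "CO"),
    temporal     = c("TP", "STGa", "STGp", "MTGa", "MTGp", "MTGto", "ITGa",
                     "ITGp", "ITGto", "TFCa", "TFCp", "TOF", "PP", "HG", "PT"),
    occipital    = c("LOs", "LOi", "ICC", "OFG", "SP", "OP"),
    subcortical  = c("IC", "PGa", "PGp", "LV", "TH", "CA", "PU", "PA", "HI",
                     "AM", "AC"),
    parietal     = c("SPL", "SMGa", "SMGp", "AG", "PCG", "CGa", "CGp", "PC",
                     "CC", "LG", "POC")
  )
  if (!full) {
    drop <- c("LV", "STGa", "MTGa", "MTGto", "ITGa", "ITGto", "TFCa", "PP",
              "LOi", "PGa", "SMGa")
    comm <- lapply(comm, function(v) setdiff(v, drop))
  }
  abbrev <- unlist(comm, use.names = FALSE)
  community <- rep(seq_along(comm), lengths(comm))
  community_name <- rep(names(comm), lengths(comm))
  # functional networks emerging after stimulus onset
  networks <- list(
    CEN = c("SPL", "MFG", "CGp", "FO"),
    SN  = c("IC", "AM", "TH", "IFGo", "CGa"),
    DMN = c("PC", "AG", "HI", "FMC", "ITGp")
  )
  net <- rep(NA_character_, length(abbrev))
  for (nm in names(networks)) net[abbrev %in% networks[[nm]]] <- nm
  out <- data.frame(
    abbrev = rep(abbrev, each = 2L),
    hemisphere = rep(c("L", "R"), times = length(abbrev)),
    community = rep(community, each = 2L),
    community_name = rep(community_name, each = 2L),
    network = rep(net, each = 2L),
    stringsAsFactors = FALSE
  )
  out$roi <- paste(out$abbrev, out$hemisphere, sep = ".")
  out[, c("roi", "abbrev", "hemisphere", "community", "community_name",
          "network")]
}

#' ROI indices (or names) belonging to a named functional network
#'
#' @param network One of "CEN", "SN", "DMN".
#' @param roi_names Optional character vector of ROI labels defining the node
#'   order; defaults to `roi_table()$roi`.
#' @return Integer indices of the network's nodes within `roi_names`.
#' @export
network_nodes <- function(network = c("CEN", "SN", "DMN"),
                          roi_names = roi_table()$roi) {
  network <- match.arg(network)
  tab <- roi_table()
  members <- tab$roi[!is.na(tab$network) & tab$network == network]
  idx <- which(roi_names %in% members)
  if (length(idx) == 0L)
    stop("no ROI in `roi_names` belongs to network ", network)
  idx
}
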