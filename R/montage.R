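#' Electrode montages
#'
#' A montage is the labelled set of electrode positions used throughout the
#' package: scalp channels lie on the unit sphere (x = right, y = anterior,
#' z = up, origin at the head centre), electrooculogram (EOG) channels sit
#' off-scalp around the right eye and at the outer canthi. Named
#' region-of-interest (ROI) label sets travel with the montage.
#'
#' @name montage
NULL

# Coronal-chain sagittal angles (degrees from the vertex, positive anterior).
# Rows follow extended 10-5 nomenclature; temporal rows FT/T/TP share the
# angles of FC/C/CP.
.chain_angles <- c(
  Fp = 72, AF = 54, AFF = 45, F = 36, FFC = 27, FC = 18, FT = 18,
  FCC = 9, C = 0, T = 0, CCP = -9, CP = -18, TP = -18, CPP = -27,
  P = -36, PPO = -45, PO = -54, POI = -63, O = -72, OI = -81, I = -90
)

# Left-hemisphere label inventory; right hemisphere is the parity mirror and
# the midline carries the z labels. 18 midline + 2 x 55 lateral = 128.
.midline_labels <- c(
  "Fpz", "AFz", "AFFz", "Fz", "FFCz", "FCz", "FCCz", "Cz", "CCPz",
  "CPz", "CPPz", "Pz", "PPOz", "POz", "POIz", "Oz", "Oiz", "Iz"
)
.left_labels <- c(
  "Fp1", "AF3", "AF7", "AFF1", "AFF5", "F1", "F3", "F5", "F7", "F9",
  "FFC1", "FFC3", "FFC5", "FC1", "FC3", "FC5", "FT7", "FT9",
  "FCC1", "FCC3", "FCC5", "C1h", "C1", "C3", "C5", "T7",
  "CCP1", "CCP3", "CCP5", "CP1", "CP3", "CP5", "TP7", "TP9",
  "CPP1", "CPP3", "CPP5h", "CPP5", "P1", "P3", "P5", "P7", "P9",
  "PPO1", "PPO3", "PPO5", "PO3", "PO5", "PO7", "PO9", "PO11",
  "POI1", "O1", "OI1", "I1"
)

.parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+h?)$", label))[[1]]
  if (length(m) == 0L) stop("cannot parse electrode label: ", label)
  chain <- m[2]
  suffix <- m[3]
  if (chain == "Oi") chain <- "OI"   # paper-style capitalisation of Oiz
  if (suffix == "z") {
    list(chain = chain, index = 0L, half = FALSE, midline = TRUE)
  } else {
    half <- grepl("h$", suffix)
    idx <- as.integer(sub("h$", "", suffix))
    list(chain = chain, index = idx, half = half, midline = FALSE)
  }
}

#' Mirror an electrode label across the midline
#'
#' Odd lateral indices are left-hemisphere, even indices their right
#' homologues (P7 <-> P8, PO9 <-> PO10, CPP5h <-> CPP6h); midline labels are
#' their own mirror.
#'
#' @param labels character vector of electrode labels.
#' @return character vector of mirrored labels.
#' @export
label_mirror <- function(labels) {
  vapply(labels, function(lb) {
    p <- .parse_label(lb)
    if (p$midline) return(lb)
    new_idx <- if (p$index %% 2L == 1L) p$index + 1L else p$index - 1L
    chain <- sub("^OI$", "OI", p$chain)
    prefix <- sub(paste0("(z|[0-9]+h?)$"), "", lb)
    paste0(prefix, new_idx, if (p$half) "h" else "")
  }, character(1), USE.NAMES = FALSE)
}

# Unit-sphere position from chain angle beta (deg, + anterior) and lateral
# arc fraction f (0 = midline, 1 = ear level), sign = hemisphere (-1 left).
# For f <= 0.8 the electrode lies on the great-circle arc from the midline
# point towards the ipsilateral preauricular point; beyond 0.8 the polar
# angle keeps increasing at fixed azimuth so that low rows (indices 9, 11)
# descend below the equator without collapsing onto the ear.
.position_from <- function(beta_deg, f, sign) {
  beta <- beta_deg * pi / 180
  M <- c(0, sin(beta), cos(beta))
  L <- c(sign, 0, 0)
  slerp <- function(ff) M * cos(ff * pi / 2) + L * sin(ff * pi / 2)
  if (f <= 0.8) return(slerp(f))
  p8 <- slerp(0.8)
  theta8 <- acos(p8[3])
  az <- atan2(p8[2], p8[1])
  theta <- theta8 + (f - 0.8) * pi / 2
  c(sin(theta) * cos(az), sin(theta) * sin(az), cos(theta))
}

.lateral_fraction <- function(index, half, chain) {
  # T7/T8 sit at ear level; other index-7 electrodes at 0.8 of the arc
  if (chain %in% c("T")) return(1.0)
  f <- 0.2 * ceiling(index / 2)
  if (chain %in% c("FT", "TP") && index >= 7) f <- f + 0.1  # temporal rows hug the ear
  if (half) f <- f - 0.1
  f
}

#' Construct the standard 128-channel montage
#'
#' Builds a 128-electrode scalp layout in extended 10-5 nomenclature
#' (including the low occipito-temporal rows PO9/PO10, PO11/PO12, POI1/POI2,
#' OI1/OI2, I1/I2 used for FPVS category-change responses) plus four EOG
#' channels: `HEOGL`/`HEOGR` at the outer canthi and `VEOGU`/`VEOGL` above
#' and below the right eye. Two a priori occipito-temporal ROIs of nine
#' lateralised electrodes each are attached as named label sets.
#'
#' @return an object of class `fpvs_montage`: list with elements
#'   `channels` (data.frame: label, x, y, z, type) and `roi_sets`
#'   (named list of label vectors).
#' @export
standard_montage <- function() {
  labels <- c(.midline_labels, .left_labels, label_mirror(.left_labels))
  pos <- t(vapply(labels, function(lb) {
    p <- .parse_label(lb)
    beta <- .chain_angles[[p$chain]]
    if (p$midline) return(.position_from(beta, 0, -1))
    sgn <- if (p$index %% 2L == 1L) -1 else 1
    .position_from(beta, .lateral_fraction(p$index, p$half, p$chain), sgn)
  }, numeric(3)))
  channels <- data.frame(
    label = labels,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    type = "scalp",
    stringsAsFactors = FALSE
  )
  eog <- data.frame(
    label = c("HEOGL", "HEOGR", "VEOGU", "VEOGL"),
    x = c(-0.95, 0.95, 0.30, 0.30),
    y = c(0.45, 0.45, 0.95, 0.92),
    z = c(-0.25, -0.25, -0.15, -0.40),
    type = "eog",
    stringsAsFactors = FALSE
  )
  channels <- rbind(channels, eog)
  rownames(channels) <- NULL
  roi_left <- c("CPP5h", "P5", "P7", "P9", "PPO3", "PPO5", "PO7", "PO9", "PO11")
  montage <- structure(
    list(
      channels = channels,
      roi_sets = list(
        ot_left = roi_left,
        ot_right = label_mirror(roi_left)
      )
    ),
    class = "fpvs_montage"
  )
  validate_montage(montage)
  montage
}

#' Validate a montage object
#'
#' Checks label uniqueness, finite positions and that every ROI label is a
#' montage channel.
#'
#' @param montage an `fpvs_montage`.
#' @return the montage, invisibly; errors otherwise.
#' @export
validate_montage <- function(montage) {
  ch <- montage$channels
  if (anyDuplicated(ch$label)) stop("montage labels must be unique")
  if (!all(is.finite(as.matrix(ch[, c("x", "y", "z")]))))
    stop("montage positions must be finite")
  for (nm in names(montage$roi_sets)) {
    missing <- setdiff(montage$roi_sets[[nm]], ch$label)
    if (length(missing))
      stop("ROI '", nm, "' refers to unknown channels: ",
           paste(missing, collapse = ", "))
  }
  invisible(montage)
}

#' Restrict a montage to a channel subset
#'
#' Used to build scaled-down montages for simulation studies. EOG channels
#' are kept unless explicitly excluded; ROI sets are intersected with the
#' remaining labels.
#'
#' @param montage an `fpvs_montage`.
#' @param labels scalp labels to keep.
#' @param keep_eog keep the four EOG channels (default TRUE).
#' @return an `fpvs_montage`.
#' @export
subset_montage <- function(montage, labels, keep_eog = TRUE) {
  ch <- montage$channels
  keep <- ch$label %in% labels | (keep_eog & ch$type == "eog")
  out <- montage
  out$channels <- ch[keep, , drop = FALSE]
  rownames(out$channels) <- NULL
  out$roi_sets <- lapply(montage$roi_sets, intersect, out$channels$label)
  validate_montage(out)
  out
}

#' Scalp channel labels of a montage
#' @param montage an `fpvs_montage`.
#' @return character vector.
#' @export
scalp_labels <- function(montage) {
  montage$channels$label[montage$channels$type == "scalp"]
}

#' EOG channel labels of a montage
#' @param montage an `fpvs_montage`.
#' @return character vector.
#' @export
eog_labels <- function(montage) {
  montage$channels$label[montage$channels$type == "eog"]
}

# Euclidean (chord) distance matrix between montage channels
.montage_dist <- function(montage, labels_a, labels_b = labels_a) {
  ch <- montage$channels
  pa <- as.matrix(ch[match(labels_a, ch$label), c("x", "y", "z")])
  pb <- as.matrix(ch[match(labels_b, ch$label), c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sqrt(pmax(d2, 0))
}

#' @export
print.fpvs_montage <- function(x, ...) {
  ch <- x$channels
  cat("FPVS montage:", sum(ch$type == "scalp"), "scalp +",
      sum(ch$type == "eog"), "EOG channels\n")
  cat("ROI sets:", paste(sprintf("%s (%d)", names(x$roi_sets),
                                 lengths(x$roi_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a montage as a delimited table
#'
#' Tab-separated columns label, x, y, z, type; ROI sets are stored in a
#' commented header line as `#roi <name>: <labels, comma-separated>`.
#'
#' @param montage an `fpvs_montage`.
#' @param path file path.
#' @return `read_montage` returns an `fpvs_montage`.
#' @export
write_montage <- function(montage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(montage$roi_sets)) {
    writeLines(sprintf("#roi %s: %s", nm,
                       paste(montage$roi_sets[[nm]], collapse = ",")), con)
  }
  utils::write.table(montage$channels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  roi_lines <- grep("^#roi ", lines, value = TRUE)
  roi_sets <- list()
  for (rl in roi_lines) {
    nm <- sub("^#roi ([^:]+):.*$", "\\1", rl)
    roi_sets[[nm]] <- strsplit(sub("^#roi [^:]+: *", "", rl), ",")[[1]]
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  montage <- structure(list(channels = tab, roi_sets = roi_sets),
                       class = "fpvs_montage")
  validate_montage(montage)
  montage
}
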