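# Electrode geometry for a 64-channel 10-10 cap: positions on the unit sphere,
# midline/lateral classification, homologous left/right pairing, and the
# spatial adjacency graph used by all scalp-level cluster statistics.

# Coordinate frame: x points to the subject's right, y anterior, z up (RAS).
# Midline channels sit at x = 0; left-hemisphere channels have x < 0. All
# positions are generated analytically from standard 10-10 spherical angles,
# so the montage is reproducible without any external coordinate file.

.slerp <- function(a, b, f) {
  # geodesic interpolation between two unit vectors
  ang <- acos(max(-1, min(1, sum(a * b))))
  if (ang < 1e-12) return(a)
  (sin((1 - f) * ang) * a + sin(f * ang) * b) / sin(ang)
}

.build_positions_1010 <- function() {
  deg <- pi / 180
  pos <- list()

  # Midline: angle from the vertex along the sagittal plane (positive anterior).
  midline <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
               CPz = -18, Pz = -36, POz = -54, Oz = -72, Iz = -90)
  for (lab in names(midline)) {
    b <- midline[[lab]] * deg
    pos[[lab]] <- c(0, sin(b), cos(b))
  }

  # Outer ring (10% line): polar angle 72 deg from the vertex, azimuth measured
  # from the anterior midline towards the left ear.
  ring <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
            TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  for (lab in names(ring)) {
    az <- ring[[lab]] * deg
    pol <- 72 * deg
    pos[[lab]] <- c(-sin(pol) * sin(az), sin(pol) * cos(az), cos(pol))
  }
  # Ear-adjacent pair one 10% step below the TP line.
  pos[["TP9"]] <- c(-sin(90 * deg) * sin(108 * deg), sin(90 * deg) * cos(108 * deg), cos(90 * deg))

  # Intermediate electrodes: geodesic fractions along the arc from the midline
  # electrode of each coronal row out to its 10% line electrode.
  rows <- list(
    F  = list(mid = "Fz",  out = "F7",  labs = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    FC = list(mid = "FCz", out = "FT7", labs = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    C  = list(mid = "Cz",  out = "T7",  labs = c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    CP = list(mid = "CPz", out = "TP7", labs = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    P  = list(mid = "Pz",  out = "P7",  labs = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    AF = list(mid = "AFz", out = "AF7", labs = c(AF3 = 0.5)),
    PO = list(mid = "POz", out = "PO7", labs = c(PO3 = 0.5))
  )
  for (row in rows) {
    for (lab in names(row$labs)) {
      pos[[lab]] <- .slerp(pos[[row$mid]], pos[[row$out]], row$labs[[lab]])
    }
  }

  # Right hemisphere: exact sagittal mirror of the left.
  left <- names(pos)[vapply(pos, function(p) p[1] < -1e-9, logical(1))]
  for (lab in left) {
    p <- pos[[lab]]
    pos[[.mirror_label(lab)]] <- c(-p[1], p[2], p[3])
  }
  pos
}

.mirror_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1]]
  if (length(m) == 0) return(NA_character_)
  num <- as.integer(m[3])
  paste0(m[2], if (num %% 2 == 1) num + 1 else num - 1)
}

#' Standard 64-channel 10-10 montage
#'
#' Builds the fixed 64-channel montage used throughout the package: 10 midline
#' channels (labels ending in `z`, plus `Iz`) and 54 lateral channels in 27
#' homologous left/right pairs, with unit-sphere positions generated from the
#' standard 10-10 spherical angles and a great-circle-distance adjacency graph.
#'
#' The cap identity (which 64 labels) is an explicit choice of this package;
#' it includes the ear-adjacent pair TP9/TP10 as lateral channels.
#'
#' @param neighbor_distance great-circle distance (radians on the unit sphere)
#'   below which two channels are considered spatial neighbors. The default is
#'   chosen so the median neighbor count is about 6.
#' @return An object of class `montage`: a list with `channels` (data frame of
#'   label, x, y, z, is_midline, pair) and `adjacency` (symmetric logical
#'   matrix with channel dimnames).
#' @export
standard_montage <- function(neighbor_distance = 0.46) {
  pos <- .build_positions_1010()
  labels <- names(pos)
  stopifnot(length(labels) == 64)
  xyz <- do.call(rbind, pos)
  # normalize (slerp preserves unit norm, but guard against rounding)
  xyz <- xyz / sqrt(rowSums(xyz^2))
  is_mid <- abs(xyz[, 1]) < 1e-9
  pair <- vapply(labels, function(l) {
    if (is_mid[match(l, labels)]) NA_character_ else .mirror_label(l)
  }, character(1))
  channels <- data.frame(label = labels, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         is_midline = is_mid, pair = pair,
                         stringsAsFactors = FALSE, row.names = NULL)
  m <- structure(list(channels = channels, adjacency = NULL,
                      neighbor_distance = neighbor_distance),
                 class = "montage")
  m$adjacency <- build_adjacency(m, neighbor_distance)
  m
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels (%d midline, %d lateral), %d adjacency edges\n",
              nrow(x$channels), sum(x$channels$is_midline),
              sum(!x$channels$is_midline), sum(x$adjacency) / 2))
  invisible(x)
}

#' Channel positions as a matrix
#' @param montage a `montage` object
#' @return numeric matrix (channels x 3) with row names
#' @export
montage_positions <- function(montage) {
  p <- as.matrix(montage$channels[, c("x", "y", "z")])
  rownames(p) <- montage$channels$label
  p
}

#' Homologous (mirror-symmetric) channel
#'
#' Maps a lateral 10-10 channel to its left/right mirror (e.g. `FC4` to `FC3`);
#' midline channels have no mirror and return `NA`.
#'
#' @param channel channel label
#' @param montage a `montage` object
#' @return the paired label, or `NA_character_` for midline channels
#' @export
homologous_pair <- function(channel, montage) {
  i <- match(channel, montage$channels$label)
  if (is.na(i)) stop("unknown channel label: ", channel)
  montage$channels$pair[i]
}

#' Spatial adjacency from great-circle distance
#'
#' Connects every channel pair whose great-circle distance on the unit sphere
#' is at most `neighbor_distance`. The resulting graph must be connected, since
#' cluster-based permutation statistics assume a single scalp neighborhood
#' structure.
#'
#' @param montage a `montage` object
#' @param neighbor_distance threshold in radians (> 0)
#' @return symmetric logical adjacency matrix without self-loops
#' @export
build_adjacency <- function(montage, neighbor_distance = montage$neighbor_distance) {
  if (!is.numeric(neighbor_distance) || neighbor_distance <= 0)
    stop("neighbor_distance must be > 0")
  p <- montage_positions(montage)
  cosang <- tcrossprod(p)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  d <- acos(cosang)
  adj <- d <= neighbor_distance
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (!igraph::is_connected(g))
    stop("adjacency graph is disconnected at neighbor_distance = ",
         neighbor_distance, "; increase the threshold")
  adj
}

#' Lateral (paired) channel labels
#' @param montage a `montage` object
#' @return character vector of the 54 non-midline labels
#' @export
lateral_channels <- function(montage) {
  montage$channels$label[!montage$channels$is_midline]
}

#' Write / read a montage as a plain-text table
#'
#' The on-disk format is a tab-separated table with columns
#' `label, x, y, z, is_midline, pair` -- sufficient to rebuild the montage.
#'
#' @param montage a `montage` object
#' @param path file path
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage$channels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @param neighbor_distance adjacency threshold used when rebuilding
#' @export
read_montage <- function(path, neighbor_distance = 0.46) {
  ch <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ch$pair[ch$pair == "NA" | ch$pair == ""] <- NA_character_
  m <- structure(list(channels = ch, adjacency = NULL,
                      neighbor_distance = neighbor_distance),
                 class = "montage")
  m$adjacency <- build_adjacency(m, neighbor_distance)
  m
}
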