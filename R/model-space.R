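#' Canonical eight-dipole source set
#'
#' Returns the eight equivalent-current-dipole sources used throughout the
#' package: lateral geniculate nucleus (LGN), primary visual cortex (V1),
#' pulvinar (PUL) and amygdala (AMY), each in both hemispheres, with their
#' prior MNI coordinates (mm). Right-hemisphere coordinates mirror the left
#' ones in x.
#'
#' @return A data.frame of class \code{"dcm_sources"} with columns
#'   \code{name}, \code{structure}, \code{hemisphere}, \code{x}, \code{y},
#'   \code{z} (MNI mm), one row per source, in the fixed canonical order
#'   LGN.L, LGN.R, V1.L, V1.R, PUL.L, PUL.R, AMY.L, AMY.R.
#' @examples
#' src <- build_source_set()
#' dipole_distance(src["V1.L", ], src["V1.R", ])   # 14 mm
#' @export
build_source_set <- function() {
  left <- rbind(
    LGN = c(-22, -22, -6),
    V1  = c(-7,  -85, -7),
    PUL = c(-12, -25,  7),
    AMY = c(-23, -5,  -22)
  )
  structure_names <- rownames(left)
  rows <- list()
  for (s in structure_names) {
    for (h in c("L", "R")) {
      xyz <- left[s, ]
      if (h == "R") xyz[1] <- -xyz[1]
      rows[[paste(s, h, sep = ".")]] <- data.frame(
        name = paste(s, h, sep = "."),
        structure = s,
        hemisphere = if (h == "L") "left" else "right",
        x = xyz[1], y = xyz[2], z = xyz[3],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$name
  class(out) <- c("dcm_sources", "data.frame")
  out
}

#' Euclidean distance between two dipoles
#'
#' @param a,b single rows of a \code{dcm_sources} data.frame (or any list with
#'   \code{x}, \code{y}, \code{z} in mm).
#' @return Distance in mm.
#' @export
dipole_distance <- function(a, b) {
  pa <- c(a$x, a$y, a$z); pb <- c(b$x, b$y, b$z)
  stopifnot(all(is.finite(pa)), all(is.finite(pb)))
  sqrt(sum((pa - pb)^2))
}

canonical_edges <- function(family = c("dual_route", "cortical_only")) {
  family <- match.arg(family)
  e <- list(c("LGN.L", "V1.L"), c("LGN.R", "V1.R"),
            c("V1.L", "AMY.L"), c("V1.R", "AMY.R"))
  if (family == "dual_route")
    e <- c(e, list(c("PUL.L", "AMY.L"), c("PUL.R", "AMY.R")))
  e
}

#' Build a connectivity graph over a source set
#'
#' Extrinsic connectivity for one model. Every forward edge has a reciprocal
#' backward edge; lateral connections are never used (the mask is kept for
#' forward compatibility and is always empty). Driving input enters at LGN
#' and PUL.
#'
#' @param sources a \code{dcm_sources} data.frame.
#' @param forward_edges list of length-2 character vectors \code{c(from, to)}.
#' @param interhemispheric logical; if TRUE, reciprocal coupling between
#'   homologous left/right structures is added.
#' @return List of class \code{"dcm_graph"}: logical matrices
#'   \code{forward}, \code{backward}, \code{lateral} (n x n, from in rows,
#'   to in columns) and logical vector \code{input}.
#' @export
connectivity_graph <- function(sources, forward_edges,
                               interhemispheric = FALSE) {
  n <- nrow(sources)
  nm <- sources$name
  mk <- function() matrix(FALSE, n, n, dimnames = list(nm, nm))
  fwd <- mk()
  for (e in forward_edges) fwd[e[1], e[2]] <- TRUE
  if (interhemispheric) {
    for (s in unique(sources$structure)) {
      idx <- which(sources$structure == s)
      if (length(idx) == 2) {
        fwd[idx[1], idx[2]] <- TRUE
        fwd[idx[2], idx[1]] <- TRUE
      }
    }
  }
  bwd <- t(fwd)
  diag(fwd) <- FALSE; diag(bwd) <- FALSE
  inp <- sources$structure %in% c("LGN", "PUL")
  names(inp) <- nm
  g <- list(forward = fwd, backward = bwd, lateral = mk(), input = inp)
  class(g) <- "dcm_graph"
  g
}

#' Valence-modulation specification
#'
#' The four condition-modulation patterns compared in the model space: no
#' modulation, modulation of the forward projections to the amygdala,
#' modulation of the backward projections from the amygdala, or both
#' (recurrent).
#'
#' @param pattern one of "none", "forward", "backward", "recurrent".
#' @param graph a \code{dcm_graph}.
#' @param sources the matching \code{dcm_sources}.
#' @return List of class \code{"dcm_modulation"} with \code{pattern} and
#'   logical matrix \code{b_mask} (subset of forward | backward masks).
#' @export
modulation_spec <- function(pattern = c("none", "forward", "backward", "recurrent"),
                            graph, sources) {
  pattern <- match.arg(pattern)
  amy <- sources$structure == "AMY"
  b <- graph$forward & FALSE
  if (pattern %in% c("forward", "recurrent"))
    b <- b | (graph$forward & outer(rep(TRUE, nrow(sources)), amy))
  if (pattern %in% c("backward", "recurrent"))
    b <- b | (graph$backward & outer(amy, rep(TRUE, nrow(sources))))
  m <- list(pattern = pattern, b_mask = b)
  class(m) <- "dcm_modulation"
  m
}

#' Assemble one DCM specification
#' @param family "dual_route" or "cortical_only".
#' @param pattern modulation pattern (see \code{\link{modulation_spec}}).
#' @param flags character vector of architecture flags, any of
#'   "interhemispheric", "unilateral_midline", "intrinsic_amygdala".
#' @return List of class \code{"dcm_spec"} with \code{family}, \code{sources},
#'   \code{graph}, \code{modulation}, \code{flags}, \code{name} and, when the
#'   intrinsic-amygdala flag is set, a per-node inhibitory self-gain vector.
#' @export
dcm_spec <- function(family = c("dual_route", "cortical_only"),
                     pattern = "none", flags = character(0)) {
  family <- match.arg(family)
  bad <- setdiff(flags, c("interhemispheric", "unilateral_midline",
                          "intrinsic_amygdala"))
  if (length(bad))
    stop("unknown architecture flags: ", paste(bad, collapse = ", "))
  sources <- build_source_set()
  edges <- canonical_edges(family)
  if ("unilateral_midline" %in% flags) {
    sources <- merge_midline(sources)
    edges <- lapply(edges, function(e) sub("^(LGN|PUL)\\.[LR]$", "\\1.M", e))
    edges <- unique(edges)
  }
  g <- connectivity_graph(sources, edges,
                          interhemispheric = "interhemispheric" %in% flags)
  self_inhib <- rep(0, nrow(sources))
  names(self_inhib) <- sources$name
  if ("intrinsic_amygdala" %in% flags)
    self_inhib[sources$structure == "AMY"] <- 8
  spec <- list(
    family = family, sources = sources, graph = g,
    modulation = modulation_spec(pattern, g, sources),
    flags = flags, self_inhib = self_inhib,
    name = paste(family, pattern, sep = "_")
  )
  class(spec) <- "dcm_spec"
  spec
}

# midline variant: LGN and PUL collapse to single nodes at x = 0
merge_midline <- function(sources) {
  keep <- sources[!(sources$structure %in% c("LGN", "PUL") &
                      sources$hemisphere == "right"), ]
  mid <- keep$structure %in% c("LGN", "PUL")
  keep$x[mid] <- 0
  keep$hemisphere[mid] <- "midline"
  keep$name[mid] <- paste0(keep$structure[mid], ".M")
  rownames(keep) <- keep$name
  class(keep) <- c("dcm_sources", "data.frame")
  keep
}

#' Build the compared model families
#'
#' The two families (dual-route with a pulvinar-to-amygdala connection,
#' cortical-only without it) crossed with the four valence-modulation
#' patterns: eight models for the original architecture.
#'
#' @param flags architecture flags passed to \code{\link{dcm_spec}}.
#' @param patterns modulation patterns to include (default all four).
#' @return Named list of \code{dcm_spec} objects.
#' @export
build_families <- function(flags = character(0),
                           patterns = c("none", "forward", "backward", "recurrent")) {
  out <- list()
  for (fam in c("dual_route", "cortical_only"))
    for (p in patterns)
      out[[paste(fam, p, sep = "_")]] <- dcm_spec(fam, p, flags)
  out
}

#' Enumerate architecture variants
#'
#' The original architecture (bilateral midline structures, no
#' interhemispheric connections, no intrinsic amygdala gain) plus the three
#' single-flag variants. The composition of the full supplementary variant
#' set is not reconstructible, so the enumeration is configurable rather
#' than fixed.
#'
#' @return List of character vectors of flags; the original (empty) set first.
#' @export
enumerate_architectures <- function() {
  list(original = character(0),
       interhemispheric = "interhemispheric",
       unilateral_midline = "unilateral_midline",
       intrinsic_amygdala = "intrinsic_amygdala")
}

#' Serialize a model space to JSON
#' @param specs list of \code{dcm_spec} objects (as from
#'   \code{\link{build_families}}).
#' @param file path to write; if NULL, the JSON string is returned.
#' @export
model_space_json <- function(specs, file = NULL) {
  enc <- lapply(specs, function(s) list(
    family = s$family, pattern = s$modulation$pattern,
    flags = as.list(s$flags),
    nodes = lapply(seq_len(nrow(s$sources)), function(i)
      list(name = s$sources$name[i], mni = c(s$sources$x[i], s$sources$y[i],
                                             s$sources$z[i]))),
    forward = unname(apply(s$graph$forward, 1, as.integer, simplify = FALSE)),
    backward = unname(apply(s$graph$backward, 1, as.integer, simplify = FALSE)),
    input = as.integer(s$graph$input),
    b_mask = unname(apply(s$modulation$b_mask, 1, as.integer, simplify = FALSE))
  ))
  js <- jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(file)
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat("DCM specification:", x$name, "\n")
  cat("  sources:", nrow(x$sources),
      "| forward edges:", sum(x$graph$forward),
      "| modulated edges:", sum(x$modulation$b_mask), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
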