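# Stem-loop decomposition and the functional pre-miRNA classifier.
#
# A candidate precursor is called functional when it satisfies all of:
# a stable hairpin (free energy strictly below the threshold, default
# -18 kcal/mol), at least 18 paired bases on the main stem, a simple
# (unbranched) hairpin topology, and no large loops or bulges inside the
# mature-arm regions. "Large" is unquantified in the annotation literature
# the criteria come from; the default is > 5 nt per side, configurable.

#' Mature arm intervals on a precursor
#'
#' @param arm5p,arm3p Integer vectors `c(start, end)`, 0-based half-open,
#'   relative to the precursor.
#' @return An object of class `mature_arms`.
#' @export
mature_arms <- function(arm5p, arm3p) {
  stopifnot(length(arm5p) == 2L, length(arm3p) == 2L)
  arm5p <- as.integer(arm5p); arm3p <- as.integer(arm3p)
  if (arm5p[1L] < 0L || arm5p[1L] >= arm5p[2L] || arm3p[1L] >= arm3p[2L]) {
    stop("invalid arm intervals")
  }
  if (arm5p[1L] >= arm3p[1L]) stop("arm5p must start before arm3p")
  if (arm5p[2L] > arm3p[1L]) stop("arm intervals must not overlap")
  structure(list(arm5p = arm5p, arm3p = arm3p), class = "mature_arms")
}

#' Classifier thresholds for functional pre-miRNA annotation
#'
#' @param energy_threshold Free-energy cut in kcal/mol; the energy
#'   criterion passes when the folding energy is strictly below this value.
#' @param min_stem_pairs Minimum paired bases on the main stem.
#' @param max_mature_loop Largest tolerated internal-loop side (nt) inside
#'   a mature arm.
#' @param max_mature_bulge Largest tolerated bulge (nt) inside a mature arm.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(energy_threshold = -18, min_stem_pairs = 18L,
                              max_mature_loop = 5L, max_mature_bulge = 5L) {
  stopifnot(energy_threshold < 0, min_stem_pairs > 0L,
            max_mature_loop > 0L, max_mature_bulge > 0L)
  structure(list(energy_threshold = energy_threshold,
                 min_stem_pairs = as.integer(min_stem_pairs),
                 max_mature_loop = as.integer(max_mature_loop),
                 max_mature_bulge = as.integer(max_mature_bulge)),
            class = "classifier_config")
}

#' Decompose a secondary structure into stem-loop elements
#'
#' Walks the main stem from the outermost pair toward the hairpin loop,
#' emitting helices, bulges, internal loops (a mismatch is a 1x1 internal
#' loop) and the closing hairpin loop. A multibranch loop or more than one
#' outermost helix makes the structure a non-simple hairpin; elements are
#' reported up to the branch point.
#'
#' @param structure An `rna_structure` or dot-bracket string.
#' @return A `hairpin_decomposition`: list with `elements` (each element a
#'   list with `type` in helix/bulge/internal_loop/hairpin_loop plus sizes
#'   and 0-based half-open unpaired intervals `side5`/`side3`),
#'   `is_simple_hairpin`, and `main_stem_pairs`.
#' @examples
#' decompose("((((....))))")$main_stem_pairs  # 4
#' @export
decompose <- function(structure) {
  db <- if (inherits(structure, "rna_structure")) structure$dotbracket else structure
  pt <- db_to_partner(db)
  n <- length(pt)
  top <- integer(0)
  k <- 1L
  while (k <= n) {
    if (pt[k] > k) {
      top <- c(top, k)
      k <- pt[k] + 1L
    } else k <- k + 1L
  }
  elements <- list()
  simple <- length(top) == 1L
  stem_pairs <- 0L
  emit <- function(el) elements[[length(elements) + 1L]] <<- el

  if (length(top) >= 1L) {
    # walk the 5'-most outermost helix chain
    i <- top[1L]; j <- pt[top[1L]]
    helix_len <- 0L
    helix_start <- c(i, j)
    repeat {
      helix_len <- helix_len + 1L
      stem_pairs <- stem_pairs + 1L
      inner <- if (j - i >= 2L) (i + 1L):(j - 1L) else integer(0)
      kids <- inner[pt[inner] > inner & pt[inner] <= j]
      # direct children only: those not nested in an earlier child
      if (length(kids) > 1L) {
        keep <- kids[1L]
        last_end <- pt[kids[1L]]
        for (kk in kids[-1L]) {
          if (kk > last_end) {
            keep <- c(keep, kk)
            last_end <- pt[kk]
          }
        }
        kids <- keep
      }
      if (length(kids) == 0L) {
        emit(list(type = "helix", paired_count = helix_len,
                  outer = c(helix_start[1L] - 1L, helix_start[2L])))
        emit(list(type = "hairpin_loop", size = j - i - 1L,
                  side5 = c(i, j - 1L)))
        break
      }
      if (length(kids) > 1L) {
        simple <- FALSE
        emit(list(type = "helix", paired_count = helix_len,
                  outer = c(helix_start[1L] - 1L, helix_start[2L])))
        emit(list(type = "multibranch", n_branches = length(kids)))
        break
      }
      k1 <- kids[1L]; l1 <- pt[k1]
      g5 <- k1 - i - 1L
      g3 <- j - l1 - 1L
      if (g5 == 0L && g3 == 0L) {
        i <- k1; j <- l1
        next
      }
      emit(list(type = "helix", paired_count = helix_len,
                outer = c(helix_start[1L] - 1L, helix_start[2L])))
      if (g5 == 0L || g3 == 0L) {
        side <- if (g5 > 0L) "5p" else "3p"
        iv <- if (g5 > 0L) c(i, k1 - 1L) else c(l1, j - 1L)
        emit(list(type = "bulge", side = side, size = g5 + g3,
                  side5 = if (g5 > 0L) iv else NULL,
                  side3 = if (g3 > 0L) iv else NULL))
      } else {
        emit(list(type = "internal_loop", size5 = g5, size3 = g3,
                  side5 = c(i, k1 - 1L), side3 = c(l1, j - 1L)))
      }
      i <- k1; j <- l1
      helix_len <- 0L
      helix_start <- c(i, j)
    }
  } else {
    simple <- FALSE
  }
  structure(list(elements = elements, is_simple_hairpin = simple,
                 main_stem_pairs = stem_pairs),
            class = "hairpin_decomposition")
}

# overlap of two 0-based half-open intervals
.iv_overlap <- function(a, b) max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]))

.scan_defects <- function(decomp, arms, cfg) {
  defects <- list()
  add <- function(type, size, arm, interval) {
    defects[[length(defects) + 1L]] <<- list(type = type, size = size,
                                             arm = arm, interval = interval)
  }
  arm_of <- function(iv) {
    if (is.null(iv)) return(NULL)
    if (.iv_overlap(iv, arms$arm5p) > 0L) return("5p")
    if (.iv_overlap(iv, arms$arm3p) > 0L) return("3p")
    NULL
  }
  for (el in decomp$elements) {
    if (el$type == "bulge") {
      arm <- arm_of(if (el$side == "5p") el$side5 else el$side3)
      if (!is.null(arm) && el$size > cfg$max_mature_bulge) {
        add("bulge", el$size, arm, if (el$side == "5p") el$side5 else el$side3)
      }
    } else if (el$type == "internal_loop") {
      a5 <- arm_of(el$side5)
      if (!is.null(a5) && el$size5 > cfg$max_mature_loop) {
        add("internal_loop", el$size5, a5, el$side5)
      }
      a3 <- arm_of(el$side3)
      if (!is.null(a3) && el$size3 > cfg$max_mature_loop) {
        add("internal_loop", el$size3, a3, el$side3)
      }
    }
  }
  defects
}

#' Large loops and bulges inside the mature arms
#'
#' @param decomp A `hairpin_decomposition` (simple hairpin required).
#' @param arms A `mature_arms`.
#' @param cfg A `classifier_config`.
#' @return List of defects, each with `type`, `size`, `arm` and the
#'   unpaired `interval` (0-based half-open). Empty list iff the mature
#'   regions are clean at the configured thresholds.
#' @export
mature_region_defects <- function(decomp, arms, cfg = classifier_config()) {
  if (!inherits(decomp, "hairpin_decomposition")) stop("need a hairpin_decomposition")
  if (!decomp$is_simple_hairpin) {
    stop("mature_region_defects requires a simple hairpin")
  }
  .scan_defects(decomp, arms, cfg)
}

#' Default mature arms: 22 nt abutting the hairpin loop
#'
#' @param structure An `rna_structure` or dot-bracket string with at least
#'   one pair.
#' @param arm_len Arm length in nt.
#' @return A `mature_arms`.
#' @export
default_arms <- function(structure, arm_len = 22L) {
  db <- if (inherits(structure, "rna_structure")) structure$dotbracket else structure
  pt <- db_to_partner(db)
  n <- length(pt)
  ii <- which(pt > seq_along(pt))
  if (!length(ii)) stop("cannot place arms on an unpaired structure")
  hp <- ii[.is_hairpin_closing(pt, ii)]
  p <- hp[1L]; q <- pt[p]
  mature_arms(c(max(0L, p - arm_len), p), c(q - 1L, min(n, q - 1L + arm_len)))
}

#' Classify a precursor against the functional pre-miRNA criteria
#'
#' Applies the four annotation criteria: folding energy strictly below the
#' threshold, enough paired bases on the main stem, simple hairpin
#' topology, and mature arms free of large loops/bulges. All four booleans
#' are reported independently; `functional` is their conjunction.
#'
#' @param seq An `rna_seq` or character scalar.
#' @param structure An `rna_structure` with its energy populated.
#' @param arms A `mature_arms`, or `NULL` to place 22-nt arms abutting the
#'   hairpin loop.
#' @param cfg A `classifier_config`.
#' @return An `annotation_verdict`: booleans `functional`, `energy_ok`,
#'   `stem_ok`, `mature_ok`, `hairpin_ok`; `measured` values (mfe,
#'   main_stem_pairs, largest mature loop/bulge) and the defect list.
#' @export
classify <- function(seq, structure, arms = NULL, cfg = classifier_config()) {
  seq <- as_rna_seq(seq)
  if (!inherits(structure, "rna_structure") || is.na(structure$energy)) {
    stop("structure must be an rna_structure with a populated energy")
  }
  if (nchar(structure$dotbracket) != nchar(seq$residues)) {
    stop("structure length does not match sequence")
  }
  n <- nchar(seq$residues)
  decomp <- decompose(structure)
  if (is.null(arms)) arms <- default_arms(structure)
  if (arms$arm5p[2L] > n || arms$arm3p[2L] > n) {
    stop("mature arms extend outside the precursor")
  }
  defects <- .scan_defects(decomp, arms, cfg)
  # measured largest loop/bulge in the mature regions, regardless of threshold
  all_mature <- .scan_defects(decomp, arms,
                              list(max_mature_loop = 0L, max_mature_bulge = 0L))
  sizes <- vapply(all_mature, function(d) d$size, numeric(1))
  energy_ok <- structure$energy < cfg$energy_threshold
  stem_ok <- decomp$main_stem_pairs >= cfg$min_stem_pairs
  hairpin_ok <- decomp$is_simple_hairpin
  mature_ok <- length(defects) == 0L
  structure(list(
    functional = energy_ok && stem_ok && hairpin_ok && mature_ok,
    energy_ok = energy_ok, stem_ok = stem_ok,
    mature_ok = mature_ok, hairpin_ok = hairpin_ok,
    measured = list(
      mfe = structure$energy,
      main_stem_pairs = decomp$main_stem_pairs,
      largest_mature_defect = if (length(sizes)) max(sizes) else 0L),
    defects = defects, arms = arms), class = "annotation_verdict")
}

#' @export
print.annotation_verdict <- function(x, ...) {
  cat(sprintf(
    "annotation_verdict: %s (energy %s, stem %s, mature %s, hairpin %s)\n",
    if (x$functional) "functional" else "not functional",
    x$energy_ok, x$stem_ok, x$mature_ok, x$hairpin_ok))
  cat(sprintf("  mfe %.2f kcal/mol, %d stem pairs, largest mature defect %d nt\n",
              x$measured$mfe, x$measured$main_stem_pairs,
              as.integer(x$measured$largest_mature_defect)))
  invisible(x)
}
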