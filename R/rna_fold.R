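# Secondary-structure prediction and energy evaluation for short RNAs.
#
# Two energy models are supported: a unit-pair model (-1 kcal/mol per
# allowed pair, loops free) used for synthetic ground truth and oracle
# testing, and a simplified nearest-neighbor model (stacking energies plus
# loop-length penalties at 37 C) loaded from a plain-text parameter table.
# Pseudoknots are excluded; GU wobble pairs are allowed throughout.

.RNA_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.pair_allowed <- function(a, b) paste0(a, b) %in% .RNA_PAIRS

#' RNA sequence
#'
#' Construct a validated RNA sequence. DNA input is accepted: `T` is
#' converted to `U` on ingest and case is ignored.
#'
#' @param residues Character scalar over `A`, `C`, `G`, `U` (or `T`).
#' @param id Optional identifier.
#' @return An object of class `rna_seq` with fields `id` and `residues`
#'   (always uppercase RNA alphabet, 5' to 3').
#' @examples
#' rna_seq("ggtaac", id = "x")$residues  # "GGUAAC"
#' @export
rna_seq <- function(residues, id = "") {
  stopifnot(is.character(residues), length(residues) == 1L)
  r <- chartr("Tt", "Uu", residues)
  r <- toupper(r)
  if (nchar(r) == 0L) stop("empty RNA sequence")
  if (grepl("[^ACGU]", r)) stop("invalid residues in RNA sequence: ", residues)
  structure(list(id = as.character(id), residues = r), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("rna_seq %s (%d nt)\n%s\n", x$id, nchar(x$residues), x$residues))
  invisible(x)
}

as_rna_seq <- function(x, id = "") {
  if (inherits(x, "rna_seq")) x else rna_seq(x, id = id)
}

#' Secondary structure in dot-bracket notation
#'
#' @param dotbracket Character scalar over `(`, `)`, `.`; must be balanced.
#' @param energy Folding free energy in kcal/mol (may be `NA` until
#'   evaluated).
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(dotbracket, energy = NA_real_) {
  db_to_partner(dotbracket)  # validates
  structure(list(dotbracket = dotbracket, energy = as.numeric(energy)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("rna_structure (%d nt, %s kcal/mol)\n%s\n",
              nchar(x$dotbracket),
              ifelse(is.na(x$energy), "NA", sprintf("%.2f", x$energy)),
              x$dotbracket))
  invisible(x)
}

# partner vector: pt[i] = index paired with i (1-based), 0 if unpaired
db_to_partner <- function(db) {
  ch <- .chars(db)
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad)) stop("invalid dot-bracket characters: ", paste(bad, collapse = ""))
  n <- length(ch)
  pt <- integer(n)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stk <- c(stk, i)
    } else if (ch[i] == ")") {
      if (!length(stk)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stk)) stop("unbalanced dot-bracket: unmatched '('")
  pt
}

partner_to_db <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

#' Base pairs of a structure
#'
#' @param structure An `rna_structure` (or dot-bracket string).
#' @param base Index origin of the returned coordinates (0 or 1).
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per pair.
#' @export
structure_pairs <- function(structure, base = 0L) {
  db <- if (inherits(structure, "rna_structure")) structure$dotbracket else structure
  pt <- db_to_partner(db)
  i <- which(pt > seq_along(pt))
  m <- cbind(i = i, j = pt[i])
  m + as.integer(base) - 1L
}

# ---- energy models ---------------------------------------------------------

#' Energy model for RNA folding
#'
#' `unit_pair` scores -1 kcal/mol per allowed pair (Watson-Crick plus GU)
#' and zero for every loop. `nearest_neighbor` sums stacking energies over
#' helices plus length-dependent penalties for hairpin, bulge and internal
#' loops and an affine multibranch cost; parameters are read from a
#' plain-text table (see `inst/extdata/nn_simple_params.txt` for the format
#' and the shipped simplified table). Temperature is fixed at 37 C and
#' there are no dangling-end terms.
#'
#' @param mode `"unit_pair"` or `"nearest_neighbor"`.
#' @param params Path to a parameter table (nearest-neighbor mode only);
#'   defaults to the table shipped with the package.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(mode = c("unit_pair", "nearest_neighbor"),
                         params = NULL, min_loop = 3L) {
  mode <- match.arg(mode)
  min_loop <- as.integer(min_loop)
  stopifnot(min_loop >= 0L)
  tab <- NULL
  if (mode == "nearest_neighbor") {
    if (is.null(params)) {
      params <- system.file("extdata", "nn_simple_params.txt",
                            package = "mirexapt", mustWork = TRUE)
    }
    tab <- read_nn_params(params)
  }
  structure(list(mode = mode, min_loop = min_loop, params = tab),
            class = "energy_model")
}

#' Read a nearest-neighbor parameter table
#'
#' Whitespace-separated records, `#` comments. Sections: `STACK p1 p2 dG`
#' (closing pair then stacked pair, 5'->3' on the top strand), `HAIRPIN n
#' dG`, `BULGE n dG`, `INTERNAL n dG` (n = total unpaired), `MULTI a|b|c
#' dG` (multibranch offset, per-branch, per-unpaired).
#'
#' @param path File path.
#' @return List with `stack` (matrix indexed by pair strings), `hairpin`,
#'   `bulge`, `internal` (named numeric vectors) and `multi`.
#' @export
read_nn_params <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  fields <- strsplit(ln, "[[:space:]]+")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(.RNA_PAIRS, .RNA_PAIRS))
  hairpin <- bulge <- internal <- numeric(0)
  multi <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  for (f in fields) {
    sec <- f[[1]]
    if (sec == "STACK") {
      stack[f[[2]], f[[3]]] <- as.numeric(f[[4]])
    } else if (sec %in% c("HAIRPIN", "BULGE", "INTERNAL")) {
      v <- as.numeric(f[[3]])
      names(v) <- f[[2]]
      if (sec == "HAIRPIN") hairpin <- c(hairpin, v)
      if (sec == "BULGE") bulge <- c(bulge, v)
      if (sec == "INTERNAL") internal <- c(internal, v)
    } else if (sec == "MULTI") {
      multi[f[[2]]] <- as.numeric(f[[3]])
    } else {
      stop("unknown parameter section: ", sec)
    }
  }
  if (anyNA(stack)) stop("nearest-neighbor table must cover all stack contexts")
  if (anyNA(multi)) stop("nearest-neighbor table missing MULTI a/b/c")
  list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
       multi = multi)
}

# Jacobson-Stockmayer extrapolation beyond the tabulated lengths
# (1.75 * R * T at 37 C = 1.079 kcal/mol).
.loop_penalty <- function(tab, n) {
  if (n <= 0L) return(0)
  key <- as.character(n)
  if (key %in% names(tab)) return(unname(tab[key]))
  ns <- as.integer(names(tab))
  nmax <- max(ns)
  unname(tab[as.character(nmax)]) + 1.079 * log(n / nmax)
}

# ---- energy evaluation -----------------------------------------------------

# loop decomposition of a partner vector: list of loops, each
# list(type, closing = c(i, j) or NULL for exterior, children = list of
# c(k, l), unpaired = int count, sides = for bulge/internal the per-side
# unpaired runs as 1-based [start, end] inclusive (or NULL))
.decompose_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  walk <- function(i, j, closing) {
    # scan children of the region (i..j), closing pair may be NULL
    children <- list()
    unpaired_runs <- list()
    k <- i
    run_start <- NA_integer_
    unpaired <- 0L
    while (k <= j) {
      if (pt[k] > k) {
        if (!is.na(run_start)) {
          unpaired_runs[[length(unpaired_runs) + 1L]] <- c(run_start, k - 1L)
          run_start <- NA_integer_
        }
        children[[length(children) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else if (pt[k] == 0L) {
        if (is.na(run_start)) run_start <- k
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else {
        stop("inconsistent pairing")  # nocov
      }
    }
    if (!is.na(run_start)) {
      unpaired_runs[[length(unpaired_runs) + 1L]] <- c(run_start, j)
    }
    type <- if (is.null(closing)) {
      "exterior"
    } else if (length(children) == 0L) {
      "hairpin"
    } else if (length(children) == 1L) {
      k1 <- children[[1L]][1L]
      l1 <- children[[1L]][2L]
      g5 <- k1 - closing[1L] - 1L
      g3 <- closing[2L] - l1 - 1L
      if (g5 == 0L && g3 == 0L) "stack"
      else if (g5 == 0L || g3 == 0L) "bulge"
      else "internal"
    } else {
      "multibranch"
    }
    loops[[length(loops) + 1L]] <<- list(
      type = type, closing = closing, children = children,
      unpaired = unpaired, runs = unpaired_runs)
    for (ch in children) walk(ch[1L] + 1L, ch[2L] - 1L, ch)
  }
  walk(1L, n, NULL)
  loops
}

.loop_energy_nn <- function(loop, seqc, par) {
  cl <- loop$closing
  switch(loop$type,
    exterior = 0,
    hairpin = .loop_penalty(par$hairpin, loop$unpaired),
    stack = {
      ch <- loop$children[[1L]]
      p1 <- paste0(seqc[cl[1L]], seqc[cl[2L]])
      p2 <- paste0(seqc[ch[1L]], seqc[ch[2L]])
      par$stack[p1, p2]
    },
    bulge = .loop_penalty(par$bulge, loop$unpaired),
    internal = .loop_penalty(par$internal, loop$unpaired),
    multibranch = par$multi[["a"]] + par$multi[["b"]] * length(loop$children) +
      par$multi[["c"]] * loop$unpaired
  )
}

#' Evaluate the free energy of a structure
#'
#' Deterministic energy of a given sequence/structure pair under an energy
#' model. Under `unit_pair` this is -1 times the number of pairs; under
#' `nearest_neighbor` the structure is decomposed into loops (hairpin,
#' stack, bulge, internal, multibranch, exterior) and per-loop terms from
#' the parameter table are summed.
#'
#' @param seq An `rna_seq` (or character scalar).
#' @param structure An `rna_structure` or dot-bracket string.
#' @param model An `energy_model`.
#' @return Energy in kcal/mol.
#' @examples
#' m <- energy_model("unit_pair")
#' evaluate_energy("GGGAAACCC", "(((...)))", m)  # -3
#' @export
evaluate_energy <- function(seq, structure, model) {
  seq <- as_rna_seq(seq)
  db <- if (inherits(structure, "rna_structure")) structure$dotbracket else structure
  if (nchar(db) != nchar(seq$residues)) {
    stop("structure length does not match sequence length")
  }
  pt <- db_to_partner(db)
  seqc <- .chars(seq$residues)
  ii <- which(pt > seq_along(pt))
  if (length(ii)) {
    ok <- .pair_allowed(seqc[ii], seqc[pt[ii]])
    if (!all(ok)) {
      stop("invalid structure: non-complementary pair at position ",
           ii[which(!ok)[1L]])
    }
  }
  # enforce the hairpin-loop minimum
  if (length(ii) && any(pt[ii] - ii - 1L < model$min_loop & .is_hairpin_closing(pt, ii))) {
    stop("hairpin loop shorter than min_loop")
  }
  if (model$mode == "unit_pair") return(-1 * length(ii))
  loops <- .decompose_loops(pt)
  sum(vapply(loops, .loop_energy_nn, numeric(1), seqc = seqc, model$params))
}

.is_hairpin_closing <- function(pt, ii) {
  vapply(ii, function(i) {
    j <- pt[i]
    if (j - i - 1L <= 0L) return(TRUE)
    all(pt[(i + 1L):(j - 1L)] == 0L)
  }, logical(1))
}

# ---- folding ---------------------------------------------------------------

#' Predict the minimum free energy structure
#'
#' Dynamic-programming fold over nested (pseudoknot-free) structures with a
#' minimum hairpin-loop size. Under `unit_pair` this is a maximum-pairing
#' recursion; under `nearest_neighbor` a loop-based recursion with helix
#' stacks, bounded-size bulge/internal loops and affine multibranch loops.
#' The returned energy is minimal over all structures that
#' `enumerate_structures()` would produce for the same model. Traceback is
#' deterministic: when alternatives tie, pairing the 5'-most free base is
#' preferred, then the partner extending the current helix furthest.
#'
#' @param seq An `rna_seq` or character scalar.
#' @param model An `energy_model`.
#' @param max_interior Largest total unpaired span considered for a single
#'   bulge/internal loop (nearest-neighbor mode).
#' @return An `rna_structure` with its energy populated.
#' @examples
#' fold_mfe("GGGAAACCC", energy_model("unit_pair"))
#' @export
fold_mfe <- function(seq, model, max_interior = 30L) {
  seq <- as_rna_seq(seq)
  res <- if (model$mode == "unit_pair") {
    .fold_unit(seq$residues, model$min_loop)
  } else {
    .fold_nn(seq$residues, model, max_interior)
  }
  st <- rna_structure(partner_to_db(res$pt))
  st$energy <- evaluate_energy(seq, st, model)
  st
}

.fold_unit <- function(residues, min_loop) {
  seqc <- .chars(residues)
  n <- length(seqc)
  if (n < min_loop + 2L) return(list(pt = integer(n)))
  canpair <- outer(seqc, seqc, function(a, b) paste0(a, b) %in% .RNA_PAIRS)
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]
      ks <- (i + min_loop + 1L):j
      ks <- ks[canpair[i, ks]]
      for (k in ks) {
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        outer_ <- if (k + 1L <= j) M[k + 1L, j] else 0L
        cand <- 1L + inner + outer_
        if (cand > best) best <- cand
      }
      M[i, j] <- best
    }
  }
  pt <- integer(n)
  tb <- function(i, j) {
    while (i < j) {
      if (j - i < min_loop + 1L) return(invisible())
      target <- M[i, j]
      if (target == M[i + 1L, j]) {
        # prefer pairing i if some pairing also attains the optimum
        paired <- FALSE
        for (k in j:(i + min_loop + 1L)) {
          if (!canpair[i, k]) next
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          outer_ <- if (k + 1L <= j) M[k + 1L, j] else 0L
          if (1L + inner + outer_ == target) {
            pt[i] <<- k; pt[k] <<- i
            if (k - 1L >= i + 1L) tb(i + 1L, k - 1L)
            i <- k + 1L
            paired <- TRUE
            break
          }
        }
        if (!paired) i <- i + 1L
      } else {
        for (k in j:(i + min_loop + 1L)) {
          if (!canpair[i, k]) next
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          outer_ <- if (k + 1L <= j) M[k + 1L, j] else 0L
          if (1L + inner + outer_ == target) {
            pt[i] <<- k; pt[k] <<- i
            if (k - 1L >= i + 1L) tb(i + 1L, k - 1L)
            i <- k + 1L
            break
          }
        }
      }
    }
  }
  tb(1L, n)
  list(pt = pt)
}

.fold_nn <- function(residues, model, max_interior) {
  seqc <- .chars(residues)
  n <- length(seqc)
  min_loop <- model$min_loop
  par <- model$params
  INF <- 1e9
  if (n < min_loop + 2L) return(list(pt = integer(n)))
  canpair <- outer(seqc, seqc, function(a, b) paste0(a, b) %in% .RNA_PAIRS)
  pairstr <- outer(seqc, seqc, paste0)
  hp <- vapply(0:n, function(k) .loop_penalty(par$hairpin, k), numeric(1))
  bu <- vapply(0:n, function(k) .loop_penalty(par$bulge, k), numeric(1))
  il <- vapply(0:n, function(k) .loop_penalty(par$internal, k), numeric(1))
  ma <- par$multi[["a"]]; mb <- par$multi[["b"]]; mc <- par$multi[["c"]]

  V <- matrix(INF, n, n)   # energy given (i,j) paired
  WM <- matrix(INF, n, n)  # multiloop segment, >= 1 branch

  two_loop <- function(i, j) {
    # best stack/bulge/internal closing (i,j) with inner pair (k,l)
    best <- INF
    kmax <- min(i + 1L + max_interior, j - min_loop - 2L)
    if (kmax < i + 1L) return(best)
    for (k in (i + 1L):kmax) {
      g5 <- k - i - 1L
      lmin <- max(k + min_loop + 1L, j - 1L - (max_interior - g5))
      if (lmin > j - 1L) next
      ls <- lmin:(j - 1L)
      ls <- ls[canpair[k, ls] & V[k, ls] < INF / 2]
      if (!length(ls)) next
      g3 <- j - ls - 1L
      loopE <- ifelse(g5 == 0L & g3 == 0L,
                      par$stack[pairstr[i, j], pairstr[k, ls]],
                      ifelse(g5 == 0L | g3 == 0L, bu[g5 + g3 + 1L], il[g5 + g3 + 1L]))
      cand <- min(loopE + V[k, ls])
      if (cand < best) best <- cand
    }
    best
  }

  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      if (canpair[i, j]) {
        e <- hp[j - i]  # hairpin: j - i - 1 unpaired -> index offset by 1
        e <- min(e, two_loop(i, j))
        if (span >= 2L * (min_loop + 2L) + 1L) {
          h <- (i + 1L):(j - 2L)
          wm2 <- WM[i + 1L, h] + WM[cbind(h + 1L, j - 1L)]
          e <- min(e, ma + mb + min(wm2))
        }
        V[i, j] <- e
      }
      # WM
      w <- min(WM[i + 1L, j] + mc, WM[i, j - 1L] + mc)
      if (V[i, j] < INF / 2) w <- min(w, V[i, j] + mb)
      if (j > i + 1L) {
        ks <- (i + 1L):j
        w <- min(w, min(WM[i, ks - 1L] + WM[cbind(ks, j)]))
      }
      WM[i, j] <- w
    }
  }
  # exterior
  W <- numeric(n + 1L)  # W[j+1] = best over prefix 1..j
  for (j in seq_len(n)) {
    w <- W[j]
    is <- seq_len(max(j - min_loop - 1L, 0L))
    if (length(is)) {
      cand <- W[is] + V[cbind(is, j)]
      w <- min(w, min(cand))
    }
    W[j + 1L] <- w
  }

  pt <- integer(n)
  eps <- 1e-9
  tb_V <- function(i, j) {
    pt[i] <<- j; pt[j] <<- i
    target <- V[i, j]
    if (abs(target - hp[j - i]) < eps) return(invisible())
    # two-loop: prefer 5'-most inner pair (stack first), then 5'-most l
    kmax <- min(i + 1L + max_interior, j - min_loop - 2L)
    if (kmax >= i + 1L) {
      for (k in (i + 1L):kmax) {
        g5 <- k - i - 1L
        lmin <- max(k + min_loop + 1L, j - 1L - (max_interior - g5))
        if (lmin > j - 1L) next
        for (l in (j - 1L):lmin) {  # prefer largest l: smallest 3' gap first
          if (!canpair[k, l] || V[k, l] > INF / 2) next
          g3 <- j - l - 1L
          loopE <- if (g5 == 0L && g3 == 0L) par$stack[pairstr[i, j], pairstr[k, l]]
                   else if (g5 == 0L || g3 == 0L) bu[g5 + g3 + 1L]
                   else il[g5 + g3 + 1L]
          if (abs(loopE + V[k, l] - target) < eps) {
            tb_V(k, l)
            return(invisible())
          }
        }
      }
    }
    # multibranch
    if (j - i - 1L >= 2L * (min_loop + 2L)) {
      for (h in (i + 1L):(j - 2L)) {
        if (abs(ma + mb + WM[i + 1L, h] + WM[h + 1L, j - 1L] - target) < eps) {
          tb_WM(i + 1L, h)
          tb_WM(h + 1L, j - 1L)
          return(invisible())
        }
      }
    }
    stop("traceback failure in V")  # nocov
  }
  tb_WM <- function(i, j) {
    repeat {
      target <- WM[i, j]
      if (V[i, j] < INF / 2 && abs(V[i, j] + mb - target) < eps) {
        tb_V(i, j)
        return(invisible())
      }
      if (j > i + 1L) {
        split_done <- FALSE
        for (k in (i + 1L):j) {
          if (abs(WM[i, k - 1L] + WM[k, j] - target) < eps) {
            tb_WM(i, k - 1L)
            i <- k
            split_done <- TRUE
            break
          }
        }
        if (split_done) next
      }
      if (abs(WM[i + 1L, j] + mc - target) < eps) {
        i <- i + 1L
        next
      }
      if (abs(WM[i, j - 1L] + mc - target) < eps) {
        j <- j - 1L
        next
      }
      stop("traceback failure in WM")  # nocov
    }
  }
  # exterior traceback, 5'-most pairing preferred
  j <- n
  while (j >= 1L) {
    if (abs(W[j + 1L] - W[j]) < eps) {
      # j may still be pairable at equal energy; prefer pairing (5'-most i)
      paired <- FALSE
      is <- seq_len(max(j - min_loop - 1L, 0L))
      for (i in is) {
        if (V[i, j] < INF / 2 && abs(W[i] + V[i, j] - W[j + 1L]) < eps) {
          tb_V(i, j)
          j <- i - 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) j <- j - 1L
    } else {
      is <- seq_len(max(j - min_loop - 1L, 0L))
      for (i in is) {
        if (V[i, j] < INF / 2 && abs(W[i] + V[i, j] - W[j + 1L]) < eps) {
          tb_V(i, j)
          j <- i - 1L
          break
        }
      }
    }
  }
  list(pt = pt)
}

#' Enumerate all secondary structures of a short sequence
#'
#' Exhaustive generation of every nested structure over allowed pairs
#' (Watson-Crick + GU) respecting the hairpin-loop minimum, including the
#' all-unpaired structure. Intended as a brute-force oracle; refuses
#' sequences longer than `max_len`.
#'
#' @param seq An `rna_seq` or character scalar.
#' @param min_loop Minimum hairpin loop size.
#' @param max_len Guard against combinatorial blowup.
#' @return Character vector of dot-bracket strings (each appears exactly
#'   once).
#' @examples
#' enumerate_structures("GAAAC")  # "....." and "(...)"
#' @export
enumerate_structures <- function(seq, min_loop = 3L, max_len = 25L) {
  seq <- as_rna_seq(seq)
  seqc <- .chars(seq$residues)
  n <- length(seqc)
  if (n > max_len) {
    stop("sequence longer than the enumeration guard (", max_len, " nt)")
  }
  canpair <- outer(seqc, seqc, function(a, b) paste0(a, b) %in% .RNA_PAIRS)
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (i > j) return("")
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", gen(i + 1L, j))
    ks <- if (i + min_loop + 1L <= j) (i + min_loop + 1L):j else integer(0)
    ks <- ks[canpair[i, ks]]
    for (k in ks) {
      inner <- gen(i + 1L, k - 1L)
      outer_ <- gen(k + 1L, j)
      out <- c(out, as.vector(outer(paste0("(", inner, ")"), outer_, paste0)))
    }
    memo[[key]] <- out
    out
  }
  gen(1L, n)
}

# ---- Vienna format ---------------------------------------------------------

#' Read Vienna fold text
#'
#' Parses records of the form produced by standard folding tools: an
#' optional `>id` header, a sequence line, then a dot-bracket line ending
#' in the energy in parentheses, e.g. `(((...))) (-3.00)`. DNA input is
#' converted to RNA on ingest.
#'
#' @param x A file path or a character vector of lines.
#' @return A list of records, each `list(seq = rna_seq, structure =
#'   rna_structure)` with the parsed energy attached.
#' @export
read_vienna <- function(x) {
  ln <- if (length(x) == 1L && file.exists(x)) readLines(x) else
    unlist(strsplit(x, "\n", fixed = TRUE))
  ln <- ln[nzchar(trimws(ln))]
  out <- list()
  i <- 1L
  while (i <= length(ln)) {
    id <- ""
    if (startsWith(ln[i], ">")) {
      id <- sub("^>\\s*", "", ln[i])
      i <- i + 1L
    }
    if (i + 1L > length(ln)) stop("truncated Vienna record")
    sq <- rna_seq(trimws(ln[i]), id = id)
    fl <- trimws(ln[i + 1L])
    m <- regmatches(fl, regexec("^([().]+)\\s+\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)$", fl))[[1L]]
    if (length(m) != 3L) stop("malformed dot-bracket/energy line: ", fl)
    st <- rna_structure(m[2L], energy = as.numeric(m[3L]))
    if (nchar(st$dotbracket) != nchar(sq$residues)) {
      stop("structure length does not match sequence in Vienna record")
    }
    out[[length(out) + 1L]] <- list(seq = sq, structure = st)
    i <- i + 2L
  }
  out
}

#' Write Vienna fold text
#'
#' Counterpart of [read_vienna()]; round-trips with it.
#'
#' @param records A list of `list(seq, structure)` records (a single record
#'   may be passed directly).
#' @param path Optional output file; if `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written to a file.
#' @export
write_vienna <- function(records, path = NULL) {
  if (!is.null(records$seq)) records <- list(records)
  ln <- unlist(lapply(records, function(r) {
    c(paste0(">", r$seq$id),
      r$seq$residues,
      sprintf("%s (%.2f)", r$structure$dotbracket, r$structure$energy))
  }))
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}
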