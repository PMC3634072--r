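#' @useDynLib mirkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor optim rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")
RNA_BASES <- c("A", "C", "G", "U")

#' Load an RNA energy model from a key-value text file
#'
#' The model is a simplified nearest-neighbour parameterisation: a
#' stacking table over the six permitted pair types (Watson-Crick plus
#' G:U wobble) and linear penalties for hairpin loops, bulges and
#' internal loops. All energies are kcal/mol at 37 C. The shipped
#' default is loaded by [default_energy_model()].
#'
#' @param path path to a model file; see
#'   `system.file("extdata", "energy_model.txt", package = "mirkit")`
#'   for the format.
#' @return an object of class `energy_model`: the stacking matrix
#'   (6 x 6, pair types AU/UA/GC/CG/GU/UG), loop-penalty coefficients,
#'   `min_loop` and `max_interior`.
#' @export
read_energy_model <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")

  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  pars <- list()
  for (tk in toks) {
    if (tk[1] == "stack") {
      if (length(tk) != 4 || !all(tk[2:3] %in% PAIR_TYPES))
        stop("malformed stack entry: ", paste(tk, collapse = " "))
      e <- as.numeric(tk[4])
      stack[tk[2], tk[3]] <- e
      stack[tk[3], tk[2]] <- e
    } else {
      if (length(tk) != 2) stop("malformed entry: ", paste(tk, collapse = " "))
      pars[[tk[1]]] <- as.numeric(tk[2])
    }
  }
  if (anyNA(stack)) stop("incomplete stacking table in ", path)
  needed <- c("hairpin_base", "hairpin_slope", "bulge_base", "bulge_slope",
              "internal_base", "internal_slope", "min_loop", "max_interior")
  missing <- setdiff(needed, names(pars))
  if (length(missing)) stop("model file lacks: ", paste(missing, collapse = ", "))
  if (any(stack > 0)) stop("stack energies must be <= 0")
  if (pars$min_loop < 3) stop("min_loop must be >= 3")

  model <- c(list(stack = stack), pars[needed])
  class(model) <- "energy_model"
  model
}

#' @rdname read_energy_model
#' @export
default_energy_model <- function() {
  path <- system.file("extdata", "energy_model.txt", package = "mirkit")
  read_energy_model(path)
}

#' @export
print.energy_model <- function(x, ...) {
  cat("RNA energy model (simplified nearest-neighbour, kcal/mol)\n")
  cat("  stacking range:", min(x$stack), "to", max(x$stack), "\n")
  cat(sprintf("  hairpin loop: %.2f + %.2f*(n-%d); bulge: %.2f + %.2f*n; internal: %.2f + %.2f*(n1+n2)\n",
              x$hairpin_base, x$hairpin_slope, x$min_loop,
              x$bulge_base, x$bulge_slope, x$internal_base, x$internal_slope))
  cat("  min_loop:", x$min_loop, " max_interior:", x$max_interior, "\n")
  invisible(x)
}

## Loop penalty accessors (used by the folding engine and by the
## independent energy re-derivation in structure_energy()).

hairpin_penalty <- function(model, n) {
  stopifnot(n >= model$min_loop)
  model$hairpin_base + model$hairpin_slope * (n - model$min_loop)
}

bulge_penalty <- function(model, n) model$bulge_base + model$bulge_slope * n

internal_penalty <- function(model, n1, n2)
  model$internal_base + model$internal_slope * (n1 + n2)

base_index <- function(chars) {
  i <- match(chars, RNA_BASES)
  i[is.na(i)] <- 5L  # N and anything else: never pairs
  i
}

seq_to_int <- function(seq) base_index(strsplit(seq, "")[[1]]) - 1L

pair_type <- function(x, y) {
  p <- paste0(x, y)
  ifelse(p %in% PAIR_TYPES, p, NA_character_)
}

can_pair <- function(x, y) !is.na(pair_type(x, y))

## 16x16 stacking matrix indexed by (outer 5'base*4+3'base) for C++;
## invalid pairs get +1e9.
stack16 <- function(model) {
  m <- matrix(1e9, 16, 16)
  for (p1 in PAIR_TYPES) for (p2 in PAIR_TYPES) {
    i <- (match(substr(p1, 1, 1), RNA_BASES) - 1L) * 4L +
      match(substr(p1, 2, 2), RNA_BASES) - 1L
    j <- (match(substr(p2, 1, 1), RNA_BASES) - 1L) * 4L +
      match(substr(p2, 2, 2), RNA_BASES) - 1L
    m[i + 1L, j + 1L] <- model$stack[p1, p2]
  }
  m
}

model_params <- function(model) {
  list(stack16 = stack16(model),
       hairpin_base = model$hairpin_base, hairpin_slope = model$hairpin_slope,
       bulge_base = model$bulge_base, bulge_slope = model$bulge_slope,
       internal_base = model$internal_base, internal_slope = model$internal_slope,
       min_loop = as.integer(model$min_loop),
       max_interior = as.integer(model$max_interior))
}

#' Recompute the free energy of a dot-bracket structure
#'
#' Independent additive re-derivation of a single-stem structure's
#' energy from its dot-bracket string and the model tables: the sum of
#' stacking terms for adjacent pairs, bulge/internal-loop penalties for
#' interrupted steps, and the terminal hairpin-loop penalty. Used to
#' verify that energies reported by the folding engine are additive.
#'
#' @param seq RNA sequence (character scalar).
#' @param structure dot-bracket string of the same length with one stem.
#' @param model an `energy_model`.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, structure, model) {
  stopifnot(nchar(seq) == nchar(structure))
  ch <- strsplit(structure, "")[[1]]
  bs <- strsplit(seq, "")[[1]]
  op <- which(ch == "(")
  cl <- which(ch == ")")
  if (length(op) != length(cl)) stop("unbalanced structure")
  if (length(op) == 0) return(0)
  # single stem: k-th '(' pairs with k-th ')' from the end
  pairs <- cbind(op, rev(cl))
  if (any(pairs[, 1] >= pairs[, 2])) stop("crossing or invalid structure")
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    pt <- pair_type(bs[pairs[k, 1]], bs[pairs[k, 2]])
    if (is.na(pt)) stop("non-pairable bases at structure pair ", k)
    if (k > 1) {
      d1 <- pairs[k, 1] - pairs[k - 1, 1] - 1L
      d2 <- pairs[k - 1, 2] - pairs[k, 2] - 1L
      if (d1 == 0 && d2 == 0) {
        p_out <- pair_type(bs[pairs[k - 1, 1]], bs[pairs[k - 1, 2]])
        e <- e + model$stack[p_out, pt]
      } else if (d1 == 0 || d2 == 0) {
        e <- e + bulge_penalty(model, d1 + d2)
      } else {
        e <- e + internal_penalty(model, d1, d2)
      }
    }
  }
  n_loop <- pairs[nrow(pairs), 2] - pairs[nrow(pairs), 1] - 1L
  if (n_loop < model$min_loop) stop("terminal loop shorter than min_loop")
  unname(e + hairpin_penalty(model, n_loop))
}
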