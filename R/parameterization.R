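#' Flory-Huggins interaction parameter from solubility parameters
#'
#' chi_ij = (v / (R T)) (delta_i - delta_j)^2, with delta in (J/cm^3)^(1/2),
#' v the molar volume in cm^3/mol, T in kelvin and R = 8.314 J/(mol K), so
#' that chi is dimensionless.
#'
#' @param delta_i,delta_j Hildebrand solubility parameters, (J/cm^3)^(1/2).
#' @param v Molar volume of the pair, cm^3/mol (conventionally the mean of
#'   the two components' molar volumes).
#' @param T Absolute temperature, kelvin.
#' @return Dimensionless chi (>= 0, symmetric in i and j).
#' @examples
#' flory_huggins_chi(23, 18, v = 100, T = 298.15)  # ~1.009
#' @export
flory_huggins_chi <- function(delta_i, delta_j, v, T = 298.15) {
  if (any(v <= 0)) stop("molar volume must be positive")
  if (any(T <= 0)) stop("temperature must be positive")
  R <- 8.314  # J / (mol K)
  (v / (R * T)) * (delta_i - delta_j)^2
}

#' Map a Flory-Huggins parameter to a DPD repulsion parameter
#'
#' a_ij = 25 + 3.50 chi_ij (reduced DPD energy units at rho = 3).
#'
#' @param chi Dimensionless Flory-Huggins parameter.
#' @return Repulsion parameter a_ij.
#' @examples
#' chi_to_repulsion(0)   # 25
#' chi_to_repulsion(10)  # 60
#' @export
chi_to_repulsion <- function(chi) {
  if (any(chi < 0)) warning("negative chi: repulsion below the like-pair baseline")
  25 + 3.50 * chi
}

#' Invert the repulsion mapping
#'
#' @param a Repulsion parameter (reduced).
#' @return chi = (a - 25) / 3.50.
#' @export
repulsion_to_chi <- function(a) {
  (a - 25) / 3.50
}

new_interaction_matrix <- function(species, a) {
  dimnames(a) <- list(species, species)
  structure(list(species = species, a = a), class = "dpd_matrix")
}

#' Repulsion between two bead species
#'
#' @param matrix A \code{dpd_matrix}.
#' @param i,j Bead species names.
#' @export
repulsion <- function(matrix, i, j) {
  if (!all(c(i, j) %in% matrix$species)) {
    stop("species not covered: ",
         paste(setdiff(c(i, j), matrix$species), collapse = ", "))
  }
  matrix$a[i, j]
}

#' Load a DPD interaction matrix from a structured text document
#'
#' The document is a whitespace-separated table: comment lines start with
#' \code{#}, a \code{species} line names the bead species in order, and the
#' following lines give a lower-triangular (or full) block of repulsion
#' parameters in the same order.  The result is symmetrized and validated
#' for positivity; a full matrix must be symmetric to 1e-9.
#'
#' Two documents ship with the package, selected by
#' \code{\link{default_interaction_matrix}}: the lipopeptide system
#' (\code{G W F C S K LA}) and the vitamin E system (\code{W CHR C5 LA}),
#' both with like-pair repulsion 78 on the diagonal.
#'
#' @param source Path to the document.
#' @return A \code{dpd_matrix}.
#' @export
load_interaction_matrix <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sp_line <- grep("^species\\b", lines, value = TRUE)
  if (length(sp_line) != 1) stop("document must contain one 'species' line")
  species <- strsplit(sp_line, "\\s+")[[1]][-1]
  S <- length(species)
  rows <- lines[!startsWith(lines, "species")]
  if (length(rows) != S) stop("expected ", S, " matrix rows, got ", length(rows))
  tok <- strsplit(rows, "\\s+")
  # rows may carry a leading species label mirroring the printed tables
  labels <- vapply(tok, `[[`, "", 1)
  if (all(labels %in% species)) {
    if (!identical(labels, species)) stop("row labels out of order")
    tok <- lapply(tok, `[`, -1)
  }
  vals <- lapply(tok, as.numeric)
  if (anyNA(unlist(vals))) stop("non-numeric entry in matrix block")
  n_per_row <- lengths(vals)
  a <- matrix(NA_real_, S, S)
  if (all(n_per_row == seq_len(S))) {           # lower triangular
    for (i in seq_len(S)) a[i, seq_len(i)] <- vals[[i]]
    a[upper.tri(a)] <- t(a)[upper.tri(a)]
  } else if (all(n_per_row == rev(seq_len(S)))) {  # upper triangular
    for (i in seq_len(S)) a[i, i:S] <- vals[[i]]
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
  } else if (all(n_per_row == S)) {             # full
    a <- do.call(rbind, vals)
    if (max(abs(a - t(a))) > 1e-9) stop("asymmetric table")
  } else {
    stop("matrix block is neither triangular nor full")
  }
  if (any(a <= 0)) stop("repulsion parameters must be positive")
  new_interaction_matrix(species, a)
}

#' Shipped interaction matrices
#'
#' @param which \code{"pam"} (alias \code{"table1"}): water / PLA /
#'   lipopeptide systems; \code{"vitE"} (alias \code{"table2"}): water / PLA /
#'   vitamin E systems.
#' @return A \code{dpd_matrix}.
#' @examples
#' m <- default_interaction_matrix("pam")
#' repulsion(m, "W", "K")  # 26.7
#' @export
default_interaction_matrix <- function(which = c("pam", "vitE", "table1", "table2")) {
  which <- match.arg(which)
  file <- switch(which,
                 pam = , table1 = "matrix_pam.txt",
                 vitE = , table2 = "matrix_vitE.txt")
  load_interaction_matrix(system.file("extdata", file, package = "dpdnano",
                                      mustWork = TRUE))
}

#' Write an interaction matrix document
#'
#' Inverse of \code{\link{load_interaction_matrix}} (lower-triangular form);
#' round-trips bit-identically on the printed decimals.
#'
#' @param matrix A \code{dpd_matrix}.
#' @param path Output path.
#' @export
write_interaction_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("species", paste(matrix$species, collapse = " ")), con)
  for (i in seq_along(matrix$species)) {
    writeLines(paste(matrix$species[i],
                     paste(format(matrix$a[i, seq_len(i)], trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Build an interaction matrix from a solubility table
#'
#' Off-diagonal entries come from the Flory-Huggins pipeline,
#' \code{a_ij = 25 + 3.5 chi_ij} with \code{chi_ij} evaluated at the mean
#' molar volume of the pair; the like-pair diagonal is a convention, not a
#' consequence of the formula (chi_ii = 0 would give 25), and defaults to 78,
#' the value used for all the shipped systems.
#'
#' @param delta Named vector of solubility parameters, (J/cm^3)^(1/2).
#' @param molar_volume Named vector of molar volumes, cm^3/mol, covering the
#'   same species.
#' @param T Temperature in kelvin.
#' @param diagonal Like-pair repulsion placed on the diagonal.
#' @return A \code{dpd_matrix}.
#' @export
build_matrix_from_solubilities <- function(delta, molar_volume, T = 298.15,
                                           diagonal = 78) {
  species <- names(delta)
  if (is.null(species) || !all(species %in% names(molar_volume))) {
    stop("delta and molar_volume must be named over the same species")
  }
  if (any(delta < 0)) stop("solubility parameters must be non-negative")
  if (any(molar_volume[species] <= 0)) stop("molar volumes must be positive")
  S <- length(species)
  a <- matrix(diagonal, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i == j) next
      v <- mean(c(molar_volume[[species[i]]], molar_volume[[species[j]]]))
      a[i, j] <- chi_to_repulsion(
        flory_huggins_chi(delta[[species[i]]], delta[[species[j]]], v, T))
    }
  }
  new_interaction_matrix(species, a)
}

#' @export
print.dpd_matrix <- function(x, ...) {
  cat(sprintf("DPD interaction matrix over %d species: %s\n",
              length(x$species), paste(x$species, collapse = ", ")))
  print(round(x$a, 2))
  invisible(x)
}
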