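#' Coarse-grained bead species registry
#'
#' The bead scheme maps chemical fragments onto nine DPD bead species:
#' \describe{
#'   \item{W}{water, 3 molecules per bead (54 Da, 3.23 A radius)}
#'   \item{LA}{one lactic acid monomer of the PLA chain}
#'   \item{F}{a C3H6 unit of a palmitoyl fatty acid tail}
#'   \item{C}{modified (lipidated) cysteine of the CSKKKK peptide}
#'   \item{S}{serine}
#'   \item{K}{lysine}
#'   \item{G}{modified glycerol linker of the lipopeptides}
#'   \item{CHR}{chromanol double ring of vitamin E}
#'   \item{C5}{a five-carbon unit of the vitamin E tail}
#' }
#' Masses for W (54 Da), F (42 Da) and CHR (219 Da) are fixed by the
#' parameterization; the remaining masses default to the fragment formula
#' masses and can be overridden.  Radii other than W are metadata only: all
#' species share the single interaction cutoff \code{r_c}.
#'
#' @param masses Optional named numeric vector overriding default bead masses
#'   (daltons), e.g. \code{c(LA = 72)}.
#' @return A data frame of class \code{bead_registry} with columns
#'   \code{name}, \code{mass}, \code{radius}, \code{fragment}.
#' @examples
#' reg <- default_bead_registry()
#' reg[reg$name == "W", ]
#' @export
default_bead_registry <- function(masses = NULL) {
  reg <- data.frame(
    name = c("W", "LA", "F", "C", "S", "K", "G", "CHR", "C5"),
    mass = c(54, 72.06, 42, 160, 87.1, 128.2, 74.1, 219, 70.1),
    radius = c(3.23, 3.23, 3.23, 3.23, 3.23, 3.23, 3.23, 3.23, 3.23),
    fragment = c(
      "3 water molecules",
      "lactic acid monomer",
      "C3H6 fatty acid unit",
      "modified cysteine + thioether linker",
      "serine",
      "lysine",
      "modified glycerol",
      "chromanol double cycle",
      "C5 aliphatic unit"),
    stringsAsFactors = FALSE)
  if (!is.null(masses)) {
    unknown <- setdiff(names(masses), reg$name)
    if (length(unknown)) {
      stop("unknown bead species in mass override: ",
           paste(unknown, collapse = ", "))
    }
    reg$mass[match(names(masses), reg$name)] <- unname(masses)
  }
  if (anyDuplicated(reg$name)) stop("bead names must be unique")
  if (any(reg$mass <= 0) || any(reg$radius <= 0)) {
    stop("bead masses and radii must be positive")
  }
  class(reg) <- c("bead_registry", "data.frame")
  reg
}

#' Look up bead masses
#'
#' @param species Character vector of bead names.
#' @param registry A \code{bead_registry}.
#' @return Numeric vector of masses in daltons.
#' @export
bead_mass <- function(species, registry = default_bead_registry()) {
  idx <- match(species, registry$name)
  if (anyNA(idx)) {
    stop("missing bead species: ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  registry$mass[idx]
}

linear_bonds <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cbind(seq_len(n - 1), 2:n)
}

#' Build a molecule template
#'
#' Returns the bead-and-bond blueprint for one of the study's molecules:
#' \code{water} (a single W bead), \code{PLA_70} (a linear chain of 70 LA
#' beads), \code{vitaminE} (CHR-C5-C5-C5), \code{Pam1CSK4} (CSKKKK backbone,
#' a glycerol G bonded to C carrying one 5xF palmitoyl tail; 12 beads) and
#' \code{Pam3CSK4} (CSKKKK backbone with three 5xF tails).
#'
#' Pam3CSK4 chemistry places two tails on the glycerol unit and one directly
#' on the cysteine, giving 22 beads; set \code{pam3_glycerol = FALSE} for the
#' literal five-species variant without a G bead (21 beads, all three tails
#' on C).
#'
#' @param name One of \code{"water"}, \code{"PLA_70"}, \code{"Pam1CSK4"},
#'   \code{"Pam3CSK4"}, \code{"vitaminE"}.
#' @param registry A \code{bead_registry}; every species used by the template
#'   must be present.
#' @param pam3_glycerol Logical; include the glycerol bead in Pam3CSK4.
#' @return An object of class \code{mol_template} with elements \code{name},
#'   \code{beads} (character), \code{bonds} (2-column integer matrix),
#'   \code{kind_tags}, \code{hydrophilic} and \code{hydrophobic} bead index
#'   vectors.
#' @examples
#' tpl <- build_template("Pam1CSK4")
#' length(tpl$beads)   # 12
#' nrow(tpl$bonds)     # 11
#' @export
build_template <- function(name, registry = default_bead_registry(),
                           pam3_glycerol = TRUE) {
  tpl <- switch(
    name,
    water = list(beads = "W", bonds = matrix(integer(0), ncol = 2),
                 kind_tags = "solvent", hydrophilic = integer(0),
                 hydrophobic = integer(0)),
    PLA_70 = list(beads = rep("LA", 70), bonds = linear_bonds(70),
                  kind_tags = c("polymer", "hydrophobe"),
                  hydrophilic = integer(0), hydrophobic = 1:70),
    vitaminE = list(beads = c("CHR", "C5", "C5", "C5"),
                    bonds = linear_bonds(4), kind_tags = "hydrophobe",
                    hydrophilic = integer(0), hydrophobic = 1:4),
    Pam1CSK4 = {
      # backbone C(1)-S(2)-K(3:6); G(7) on C; tail F(8:12) on G
      beads <- c("C", "S", "K", "K", "K", "K", "G", rep("F", 5))
      bonds <- rbind(linear_bonds(6), c(1, 7), c(7, 8), linear_bonds(5) + 7)
      list(beads = beads, bonds = bonds, kind_tags = "amphiphile",
           hydrophilic = 2:6, hydrophobic = 8:12)
    },
    Pam3CSK4 = {
      if (pam3_glycerol) {
        # backbone C(1)-S(2)-K(3:6); G(7) on C; tails F(8:12), F(13:17) on G,
        # F(18:22) on C
        beads <- c("C", "S", "K", "K", "K", "K", "G", rep("F", 15))
        bonds <- rbind(linear_bonds(6), c(1, 7),
                       c(7, 8), linear_bonds(5) + 7,
                       c(7, 13), linear_bonds(5) + 12,
                       c(1, 18), linear_bonds(5) + 17)
        list(beads = beads, bonds = bonds, kind_tags = "amphiphile",
             hydrophilic = 2:6, hydrophobic = 8:22)
      } else {
        beads <- c("C", "S", "K", "K", "K", "K", rep("F", 15))
        bonds <- rbind(linear_bonds(6),
                       c(1, 7), linear_bonds(5) + 6,
                       c(1, 12), linear_bonds(5) + 11,
                       c(1, 17), linear_bonds(5) + 16)
        list(beads = beads, bonds = bonds, kind_tags = "amphiphile",
             hydrophilic = 2:6, hydrophobic = 7:21)
      }
    },
    stop("unknown template: ", name))
  missing <- setdiff(unique(tpl$beads), registry$name)
  if (length(missing)) {
    stop("missing bead species: ", paste(missing, collapse = ", "))
  }
  tpl$name <- name
  storage.mode(tpl$bonds) <- "integer"
  class(tpl) <- "mol_template"
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  n <- length(tpl$beads)
  b <- tpl$bonds
  if (nrow(b)) {
    if (any(b < 1L) || any(b > n)) stop("bond index out of range")
    if (any(b[, 1] == b[, 2])) stop("self-bond in template")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key)) stop("duplicate bond in template")
  }
  if (n > 1) {
    # connectivity by label propagation
    comp <- seq_len(n)
    repeat {
      new <- comp
      for (k in seq_len(nrow(b))) {
        m <- min(new[b[k, 1]], new[b[k, 2]])
        new[b[k, 1]] <- m; new[b[k, 2]] <- m
      }
      if (identical(new, comp)) break
      comp <- new
    }
    if (length(unique(comp)) != 1) stop("template bond graph is disconnected")
  }
  invisible(tpl)
}

#' Molecular mass of a template
#'
#' @param template A \code{mol_template}.
#' @param registry A \code{bead_registry}.
#' @return Mass in daltons (sum of bead masses; 0 for an empty template).
#' @examples
#' molecule_mass(build_template("PLA_70"))  # 70 x 72.06 = 5044.2
#' @export
molecule_mass <- function(template, registry = default_bead_registry()) {
  if (!length(template$beads)) return(0)
  sum(bead_mass(template$beads, registry))
}

#' @export
print.mol_template <- function(x, ...) {
  cat(sprintf("Molecule template '%s': %d beads, %d bonds [%s]\n",
              x$name, length(x$beads), nrow(x$bonds),
              paste(x$kind_tags, collapse = ", ")))
  cat("  composition:",
      paste(sprintf("%dx%s", as.vector(table(x$beads)[unique(x$beads)]),
                    unique(x$beads)), collapse = " + "), "\n")
  invisible(x)
}

#' Serialize molecule templates to a YAML document
#'
#' One document per molecule (beads, bonds, tags, hydrophilic/hydrophobic
#' index sets); the shipped defaults round-trip through this format.
#'
#' @param templates A list of \code{mol_template} objects.
#' @param path Output file path.
#' @export
write_templates <- function(templates, path) {
  doc <- lapply(templates, function(t) {
    list(name = t$name, beads = as.list(t$beads),
         bonds = if (nrow(t$bonds)) apply(t$bonds, 1, as.list, simplify = FALSE)
                 else list(),
         kind_tags = as.list(t$kind_tags),
         hydrophilic = as.list(t$hydrophilic),
         hydrophobic = as.list(t$hydrophobic))
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read molecule templates from a YAML document
#'
#' @param path File written by \code{\link{write_templates}}.
#' @param registry A \code{bead_registry} used to validate species.
#' @return A named list of \code{mol_template} objects.
#' @export
read_templates <- function(path, registry = default_bead_registry()) {
  doc <- yaml::read_yaml(path)
  out <- lapply(doc, function(d) {
    bonds <- if (length(d$bonds)) {
      t(vapply(d$bonds, function(p) as.integer(unlist(p)), integer(2)))
    } else matrix(integer(0), ncol = 2)
    tpl <- structure(
      list(beads = as.character(unlist(d$beads)), bonds = bonds,
           kind_tags = as.character(unlist(d$kind_tags)),
           hydrophilic = as.integer(unlist(d$hydrophilic)),
           hydrophobic = as.integer(unlist(d$hydrophobic)),
           name = d$name),
      class = "mol_template")
    missing <- setdiff(unique(tpl$beads), registry$name)
    if (length(missing)) {
      stop("missing bead species: ", paste(missing, collapse = ", "))
    }
    validate_template(tpl)
    tpl
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Default molecule template set
#'
#' @param registry A \code{bead_registry}.
#' @param pam3_glycerol Passed to \code{\link{build_template}}.
#' @return Named list of the five study templates.
#' @export
default_templates <- function(registry = default_bead_registry(),
                              pam3_glycerol = TRUE) {
  nm <- c("water", "PLA_70", "Pam1CSK4", "Pam3CSK4", "vitaminE")
  out <- lapply(nm, build_template, registry = registry,
                pam3_glycerol = pam3_glycerol)
  names(out) <- nm
  out
}
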