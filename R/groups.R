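#' Group specifications
#'
#' A `GroupSpec` names the particle index sets an analysis needs: the
#' lipid, water and additive populations, per-lipid headgroup markers, and
#' for every additive molecule its structural roles — the two backbone end
#' atoms, the atoms of the central phenylene ring (whose centroid, the
#' COR, serves as the molecule's positional marker) and the CH3/CF3
#' terminal carbons of the two side chains.
#'
#' All indices are 1-based inside R; [read_group_file()] converts from the
#' base declared in the file (`index_base`, default 0).
#'
#' @param lipids,water,additives integer index vectors (any may be empty).
#' @param molecules list with one entry per additive molecule; each entry
#'   is a list with elements `backbone_end_a`, `backbone_end_b`,
#'   `cor_ring_atoms`, `ch3_terminal`, `cf3_terminal`.
#' @param headgroup_atoms indices of per-lipid headgroup markers
#'   (phosphorus-like), optional.
#' @param n_particles total particle count used for bounds checking, or
#'   `NULL` to skip (checked again when paired with a trajectory).
#' @return an object of class `"GroupSpec"`.
#' @export
group_spec <- function(lipids = integer(), water = integer(),
                       additives = integer(), molecules = list(),
                       headgroup_atoms = integer(), n_particles = NULL) {
  spec <- structure(
    list(lipids = as.integer(lipids), water = as.integer(water),
         additives = as.integer(additives), molecules = molecules,
         headgroup_atoms = as.integer(headgroup_atoms)),
    class = "GroupSpec"
  )
  validate_group_spec(spec, n_particles)
  spec
}

mol_roles <- c("backbone_end_a", "backbone_end_b", "cor_ring_atoms",
               "ch3_terminal", "cf3_terminal")

#' Validate a group specification
#'
#' Checks role completeness, index bounds and the disjointness of the
#' lipid/additive populations. Called by [group_spec()] and by
#' [load_trajectory()] once the particle count is known.
#'
#' @param spec a `GroupSpec`.
#' @param n_particles particle count to bound-check against, or `NULL`.
#' @return `spec`, invisibly.
#' @export
validate_group_spec <- function(spec, n_particles = NULL) {
  stopifnot(inherits(spec, "GroupSpec"))
  if (length(intersect(spec$lipids, spec$additives)) > 0L)
    abort_validation("a particle cannot be both lipid and additive")
  for (i in seq_along(spec$molecules)) {
    mol <- spec$molecules[[i]]
    for (role in mol_roles) {
      idx <- mol[[role]]
      if (is.null(idx) || length(idx) == 0L)
        abort_validation("additive molecule %d is missing role '%s'", i, role)
      if (!is.null(n_particles) &&
          (any(idx < 1L) || any(idx > n_particles)))
        abort_validation(
          "role '%s' of additive molecule %d has index out of range 1..%d",
          role, i, n_particles)
    }
  }
  if (!is.null(n_particles)) {
    for (nm in c("lipids", "water", "additives", "headgroup_atoms")) {
      idx <- spec[[nm]]
      if (length(idx) && (any(idx < 1L) || any(idx > n_particles)))
        abort_validation("group '%s' has index out of range 1..%d",
                         nm, n_particles)
    }
  }
  invisible(spec)
}

#' @export
print.GroupSpec <- function(x, ...) {
  cat(sprintf(
    "<GroupSpec> %d lipids, %d water, %d additive atoms, %d molecules\n",
    length(x$lipids), length(x$water), length(x$additives),
    length(x$molecules)))
  invisible(x)
}

#' Read a group file
#'
#' Group files are YAML: top-level keys `lipids`, `water`, `additives`,
#' `headgroup_atoms` map to index lists; `molecules` is a list of
#' per-additive role maps (`backbone_end_a`, `backbone_end_b`,
#' `cor_ring_atoms`, `ch3_terminal`, `cf3_terminal`); `index_base`
#' declares the numbering convention of the file (0 by default, the
#' common convention of simulation tooling) and an optional `dt` key
#' overrides the trajectory frame spacing (ns).
#'
#' @param path path to the YAML group file.
#' @param n_particles optional particle count for bounds checking.
#' @return a `GroupSpec`; the `dt` override, if present, is attached as
#'   attribute `"dt"`.
#' @export
read_group_file <- function(path, n_particles = NULL) {
  if (!file.exists(path))
    abort_validation("group file '%s' does not exist", path)
  raw <- yaml::read_yaml(path)
  base <- raw$index_base %||% 0L
  shift <- 1L - as.integer(base)
  reindex <- function(v) if (is.null(v)) integer() else as.integer(unlist(v)) + shift
  mols <- lapply(raw$molecules %||% list(), function(m) {
    out <- lapply(mol_roles, function(role) reindex(m[[role]]))
    names(out) <- mol_roles
    out
  })
  spec <- group_spec(
    lipids = reindex(raw$lipids), water = reindex(raw$water),
    additives = reindex(raw$additives), molecules = mols,
    headgroup_atoms = reindex(raw$headgroup_atoms),
    n_particles = n_particles
  )
  if (!is.null(raw$dt)) attr(spec, "dt") <- as.numeric(raw$dt)
  spec
}

#' Write a group file
#'
#' Serialises a `GroupSpec` to the YAML layout read by
#' [read_group_file()], using the requested index base.
#'
#' @param spec a `GroupSpec`.
#' @param path output path.
#' @param index_base numbering convention to write (default 0).
#' @param dt optional frame-spacing override (ns) to embed.
#' @return `path`, invisibly.
#' @export
write_group_file <- function(spec, path, index_base = 0L, dt = NULL) {
  stopifnot(inherits(spec, "GroupSpec"))
  shift <- as.integer(index_base) - 1L
  reindex <- function(v) as.integer(v) + shift
  out <- list(index_base = as.integer(index_base))
  if (!is.null(dt)) out$dt <- dt
  for (nm in c("lipids", "water", "additives", "headgroup_atoms"))
    if (length(spec[[nm]])) out[[nm]] <- reindex(spec[[nm]])
  if (length(spec$molecules))
    out$molecules <- lapply(spec$molecules, function(m) lapply(m, reindex))
  yaml::write_yaml(out, path)
  invisible(path)
}
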