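# Electronic heme-coordination descriptors: the condensed dual descriptor,
# its ring-wise minimum, the FP8 coordination term, and the indirect
# estimate of the coordination contribution.

#' Condensed dual descriptor
#'
#' \eqn{\Delta f(r) = f^+(r) - f^-(r)}: positive values mark sites favoured
#' for nucleophilic attack, negative values for electrophilic attack.
#' Condensed-to-atom Fukui values come from external quantum chemistry and
#' are consumed as a table; the condensation scheme is not prescribed.
#'
#' @param f_plus,f_minus condensed nucleophilic / electrophilic Fukui values
#'   (vectorised).
#' @return the difference.
#' @export
dual_descriptor <- function(f_plus, f_minus) f_plus - f_minus

#' Read a per-atom Fukui table
#'
#' @param path CSV with columns \code{ligand_id}, \code{atom_index},
#'   \code{f_plus}, \code{f_minus}, \code{in_aza_ring},
#'   \code{is_coordinating_N}.
#' @return data.frame with those columns (logical flags coerced).
#' @export
read_fukui_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "atom_index", "f_plus", "f_minus", "in_aza_ring",
            "is_coordinating_N")
  if (!all(need %in% names(tbl)))
    stop("Fukui table lacks column(s): ", paste(setdiff(need, names(tbl)), collapse = ", "))
  tbl$in_aza_ring <- as.logical(tbl$in_aza_ring)
  tbl$is_coordinating_N <- as.logical(tbl$is_coordinating_N)
  tbl
}

#' Ring-wise minimum dual descriptor
#'
#' For one ligand's Fukui record, returns \code{dfs}, the smallest dual
#' descriptor over the aromatic azaheterocycle ring atoms, and \code{dfn},
#' the dual descriptor of the nitrogen that coordinates the heme iron
#' (NA when no coordinating nitrogen is marked).
#'
#' @param record data.frame for a single ligand with columns
#'   \code{f_plus}, \code{f_minus}, \code{in_aza_ring},
#'   \code{is_coordinating_N}.
#' @return list with \code{dfs} and \code{dfn}.
#' @export
smallest_dual <- function(record) {
  ring <- record[record$in_aza_ring, , drop = FALSE]
  if (nrow(ring) == 0) stop("Fukui record has no aromatic-ring atoms")
  coord <- ring[ring$is_coordinating_N, , drop = FALSE]
  if (nrow(coord) > 1)
    stop("more than one coordinating nitrogen marked in the ring")
  duals <- dual_descriptor(ring$f_plus, ring$f_minus)
  list(dfs = min(duals),
       dfn = if (nrow(coord) == 1)
         dual_descriptor(coord$f_plus, coord$f_minus) else NA_real_)
}

#' FP8: the heme-coordination descriptor term
#'
#' Linear transform of the smallest dual descriptor,
#' \eqn{38.587\,\Delta f(r)^S + 3.931}, applied only when the ligand's
#' azaheterocyclic nitrogen actually coordinates the iron (zero otherwise).
#' The transformed value enters the generalized QSAR with implicit
#' coefficient 1.
#'
#' @param dfs smallest dual descriptor (vectorised).
#' @param coordinated logical: does the ligand coordinate the heme iron?
#' @param slope,intercept transform constants.
#' @return the FP8 value(s).
#' @export
fp8_term <- function(dfs, coordinated, slope = 38.587, intercept = 3.931) {
  n <- max(length(dfs), length(coordinated))
  dfs <- rep_len(dfs, n)
  coordinated <- rep_len(coordinated, n)
  out <- numeric(n)
  out[coordinated] <- slope * dfs[coordinated] + intercept
  out
}

#' Indirectly estimated heme-coordination contribution
#'
#' Subtracts the model-explained non-coordination contributions from the
#' experimental potency: \code{residual = pIC50_exp - (C + sum over selected
#' non-FP8 features of c_i FP_i)}.  The model must not itself contain the
#' FP8 term.
#'
#' @param pIC50_exp experimental potency.
#' @param fp interaction fingerprint (named \code{FP1..FP9} vector).
#' @param model a \code{qsar_model} without FP8 among its features.
#' @return list with \code{ligand_id} (if the fingerprint carries one) and
#'   \code{residual} in pIC50 log units.
#' @export
coordination_residual <- function(pIC50_exp, fp, model) {
  if ("FP8" %in% model$features)
    stop("coordination_residual requires a model that excludes FP8")
  residual <- pIC50_exp - predict_pic50(model, fp)
  list(residual = residual)
}

#' Fit the descriptor-calibration line
#'
#' Ordinary least squares of the indirectly-estimated coordination
#' contribution on the smallest dual descriptor; the fitted constants define
#' the FP8 transform pathway.
#'
#' @param dfs numeric vector of smallest-dual-descriptor values.
#' @param residual matching coordination contributions (log units).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
fit_descriptor_line <- function(dfs, residual) {
  stopifnot(length(dfs) == length(residual))
  if (length(dfs) < 3) stop("need at least 3 (dfs, residual) pairs")
  if (stats::sd(dfs) < 1e-12) stop("degenerate fit: dfs values are constant")
  fit <- stats::lm(residual ~ dfs)
  list(slope = unname(stats::coef(fit)["dfs"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = summary(fit)$r.squared)
}
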