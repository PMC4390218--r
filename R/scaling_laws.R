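#' Quasi-homothetic scaling inputs for a reference/target specimen pair
#'
#' Bundles the measurements used to scale muscular contraction pressures and
#' forces between specimens that differ in size: body (skull model) volumes
#' V, enclosing surfaces S, and muscular insertion areas SM. In the study
#' design the reference is the adult specimen and the target the subadult.
#'
#' @param V_ref,V_tgt body volumes, mm^3.
#' @param S_ref,S_tgt enclosing surface areas, mm^2.
#' @param SM_ref,SM_tgt muscular insertion areas, mm^2.
#' @return object of class `scaling_inputs` with a derived `alpha` (linear
#'   homothety ratio, cube root of the volume ratio) when volumes are given.
#' @export
scaling_inputs <- function(V_ref = NULL, V_tgt = NULL,
                           S_ref = NULL, S_tgt = NULL,
                           SM_ref = NULL, SM_tgt = NULL) {
  chk <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || x <= 0))
      stop("`", nm, "` must be a positive scalar")
    x
  }
  s <- list(V_ref = chk(V_ref, "V_ref"), V_tgt = chk(V_tgt, "V_tgt"),
            S_ref = chk(S_ref, "S_ref"), S_tgt = chk(S_tgt, "S_tgt"),
            SM_ref = chk(SM_ref, "SM_ref"), SM_tgt = chk(SM_tgt, "SM_tgt"))
  s$alpha <- if (!is.null(V_ref) && !is.null(V_tgt))
    alpha_from_volumes(V_ref, V_tgt) else NULL
  structure(s, class = "scaling_inputs")
}

.need <- function(s, fields, fun) {
  miss <- fields[vapply(s[fields], is.null, TRUE)]
  if (length(miss))
    stop(fun, " requires scaling input(s): ", paste(miss, collapse = ", "))
}

#' Volume scaling of contraction pressure (two-thirds power law)
#'
#' Scales a muscular contraction pressure from the reference to the target
#' specimen so that the stress distribution is preserved under the
#' homothety relating the two bodies:
#' `P_tgt = P_ref * (SM_ref / SM_tgt) * (V_tgt / V_ref)^(2/3)`.
#'
#' @param P_ref reference pressure, MPa.
#' @param s a [scaling_inputs()] with volumes and insertion areas.
#' @return target pressure, MPa.
#' @export
scale_pressure_volume <- function(P_ref, s) {
  stopifnot(inherits(s, "scaling_inputs"))
  .need(s, c("V_ref", "V_tgt", "SM_ref", "SM_tgt"), "scale_pressure_volume")
  P_ref * (s$SM_ref / s$SM_tgt) * (s$V_tgt / s$V_ref)^(2 / 3)
}

#' Surface scaling of contraction pressure
#'
#' The alternative scaling based on the enclosing surface S of each body:
#' `P_tgt = P_ref * (SM_ref / SM_tgt) * (S_tgt / S_ref)`.
#'
#' @param P_ref reference pressure, MPa.
#' @param s a [scaling_inputs()] with surfaces and insertion areas.
#' @return target pressure, MPa.
#' @export
scale_pressure_area <- function(P_ref, s) {
  stopifnot(inherits(s, "scaling_inputs"))
  .need(s, c("S_ref", "S_tgt", "SM_ref", "SM_tgt"), "scale_pressure_area")
  P_ref * (s$SM_ref / s$SM_tgt) * (s$S_tgt / s$S_ref)
}

#' Volume scaling of a muscular force (two-thirds power law)
#'
#' `F_tgt = F_ref * (V_tgt / V_ref)^(2/3)` — the force transforms with the
#' square of the linear homothety ratio, i.e. the classic 2/3 power
#' relationship between force and volume (or mass) in isometric scaling.
#'
#' @param F_ref reference force, N.
#' @param V_ref,V_tgt body volumes, mm^3.
#' @return target force, N.
#' @export
scale_force_volume <- function(F_ref, V_ref, V_tgt) {
  if (!is.numeric(V_ref) || V_ref <= 0 || !is.numeric(V_tgt) || V_tgt <= 0)
    stop("volumes must be positive")
  F_ref * (V_tgt / V_ref)^(2 / 3)
}

#' Linear homothety ratio from a volume pair
#'
#' The diagonal Jacobian entry alpha of the homothetic transformation
#' relating two bodies: `alpha = (V_tgt / V_ref)^(1/3)`.
#'
#' @param V_ref,V_tgt body volumes, mm^3.
#' @return scalar ratio.
#' @export
alpha_from_volumes <- function(V_ref, V_tgt) {
  if (!is.numeric(V_ref) || V_ref <= 0 || !is.numeric(V_tgt) || V_tgt <= 0)
    stop("volumes must be positive")
  (V_tgt / V_ref)^(1 / 3)
}
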