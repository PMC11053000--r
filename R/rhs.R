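#' Hill activation
#' @param x regulator level
#' @param K half-saturation constant
#' @param n Hill exponent
#' @return value in [0, 1)
#' @keywords internal
hill <- function(x, K, n = 2) {
  xn <- (x / K)^n
  xn / (1 + xn)
}

#' Hill repression (1 at zero regulator, -> 0 at saturation)
#' @inheritParams hill
#' @keywords internal
repress <- function(x, K, n = 1) {
  1 / (1 + (x / K)^n)
}

#' Time derivative of the stress network
#'
#' Evaluates d(state)/dt under Hill-type production/degradation kinetics.
#' Each species follows basal + regulated production minus first-order
#' (or clearance-enhanced) removal; the IRS and AKT phosphorylation
#' cycles are two-state interconversions that conserve the pool totals.
#'
#' @param state `species_state` (or named numeric vector over
#'   [species_names()]).
#' @param params `kinetic_parameters`.
#' @param topology `network_topology`; validated for the required edges
#'   (the kinetics implement exactly the packaged network).
#' @return Named numeric derivative vector, same shape as `state`.
#' @export
rhs <- function(state, params, topology = network_topology()) {
  validate_state(structure(as.numeric(state), names = names(state)))
  validate_parameters(params)
  s <- as.list(state)
  drv <- rhs_raw(s, params$theta, params$totals)
  out <- unlist(drv)[species_names()]
  out
}

# Unchecked kernel shared by rhs() and the integrator.
rhs_raw <- function(s, th, totals) {
  with(as.list(th), {
    # inflammatory arm
    d_lps_dt <- b_lps + v_lps * hill(s$foxo1_cyt, K_lps_f, 2) * m_lps -
      d_lps * s$lps
    d_nfkb_dt <- b_nfkb + v_nfkb * g_inf * hill(s$lps, K_nfkb_l, 2) *
      repress(s$il10, K_nfkb_10) * m_nfkb - d_nfkb * s$nfkb
    d_tnfa_dt <- b_tnfa + v_tnfa * hill(s$nfkb, K_tnfa_n, n_tnfa) * m_tnfa -
      d_tnfa * s$tnfa
    d_il6_dt <- b_il6 + v_il6 * hill(s$nfkb, K_il6_n, 2) *
      (1 + c_il6_t * hill(s$tnfa, K_il6_t, 1)) *
      (1 + c_il6_m * hill(s$mapk, K_il6_m, 1)) * m_il6 - d_il6 * s$il6
    d_il10_dt <- b_il10 + v_il10 * hill(s$stat3, K_il10_s, 2) * m_il10 -
      d_il10 * s$il10
    d_jak1_dt <- b_jak1 + v_jak1 * hill(s$il6, K_jak1_6, 2) - d_jak1 * s$jak1
    d_stat3_dt <- b_stat3 + v_stat3 * hill(s$jak1, K_stat3_j, 2) -
      d_stat3 * s$stat3
    d_mapk_dt <- b_mapk + v_mapk * hill(s$lps, K_mapk_l, 2) - d_mapk * s$mapk

    # redox arm
    d_nrf2_dt <- b_nrf2 * m_nrf2 -
      (d_nrf2 + k_keap * g_keap * s$keap1 * m_keap1) * s$nrf2
    d_keap1_dt <- b_keap1 - d_keap1 * s$keap1
    d_sod_dt <- (b_sod + v_sod * hill(s$nrf2, K_sod_n, 2)) * m_sod / g_aox -
      d_sod * s$sod
    d_cat_dt <- (b_cat + v_cat * hill(s$nrf2, K_cat_n, 2)) * m_cat / g_aox -
      d_cat * s$cat
    d_gpx_dt <- (b_gpx + v_gpx * hill(s$nrf2, K_gpx_n, 2)) * m_gpx / g_aox -
      d_gpx * s$gpx
    d_gsh_dt <- b_gsh * m_gsh / g_aox - d_gsh * s$gsh - k_gshros * s$ros * s$gsh
    d_ros_dt <- (b_ros + v_ros * g_rosgen *
                   (1 + c_ros_n * hill(s$nfkb, K_ros_n, 2))) * m_ros -
      (d_ros + k_sodros * s$sod + k_catros * s$cat + k_gpxros * s$gpx +
         k_gshc * s$gsh + k_ampkros * s$ampk) * s$ros
    d_mda_dt <- b_mda + k_mda * s$ros - d_mda * s$mda
    d_hif1a_dt <- b_hif + v_hif * hill(s$ros, K_hif_r, 2) - d_hif * s$hif1a

    # insulin signalling
    d_foxo1_dt <- b_fox + v_fox * g_ins * hill(s$pakt, K_fox_a, 2) * m_foxo1 -
      d_fox * s$foxo1_cyt
    irs_phos <- kp_irs * g_ins *
      (1 + c_irs_m * hill(s$mapk, K_irs_m, 2)) * s$irs
    d_pirs_dt <- irs_phos - kd_irs * s$pirs
    d_irs_dt <- -d_pirs_dt
    akt_phos <- kp_akt * g_ins * hill(s$pi3k, K_akt_p, 2) * s$akt * m_pakt
    d_pakt_dt <- akt_phos - kd_akt * s$pakt
    d_akt_dt <- -d_pakt_dt
    d_pi3k_dt <- b_pi3k + v_pi3k * hill(s$insulin, K_pi3k_i, 1) - d_pi3k * s$pi3k
    d_mtor_dt <- b_mtor + v_mtor * hill(s$pakt, K_mtor_a, 1) - d_mtor * s$mtor
    d_ampk_dt <- b_ampk * repress(s$mtor, K_ampk_m) * m_ampk - d_ampk * s$ampk

    # HPA axis
    d_crh_dt <- b_crh + v_crh * hill(s$hif1a, K_crh_h, 2) *
      (1 + c_crh_6 * hill(s$il6, K_crh_6, 1)) * m_crh - d_crh * s$crh
    d_acth_dt <- b_acth + v_acth * hill(s$crh, K_acth_c, 2) * m_acth -
      d_acth * s$acth
    d_cortisol_dt <- b_cort + v_cort * hill(s$acth, K_cort_a, n_cort) *
      m_cortisol - d_cort * s$cortisol

    # renin-angiotensin system
    d_renin_dt <- b_renin + v_renin * hill(s$tnfa, K_renin_t, 3) * m_renin -
      d_renin * s$renin
    d_ang2_dt <- b_ang2 + v_ang2 * hill(s$renin, K_ang2_r, 2) * m_ang2 -
      d_ang2 * s$ang2
    d_aldo_dt <- b_aldo + v_aldo * hill(s$ang2, K_aldo_a, 2) * m_aldosterone -
      d_aldo * s$aldosterone

    # metabolic background
    d_insulin_dt <- b_insulin - d_insulin * s$insulin
    d_glucagon_dt <- b_glucagon - d_glucagon * s$glucagon
    d_glucose_dt <- b_glucose + k_glc_g * s$glucagon -
      (d_glucose + k_glc_i * s$insulin) * s$glucose

    list(lps = d_lps_dt, nfkb = d_nfkb_dt, tnfa = d_tnfa_dt, il6 = d_il6_dt,
         il10 = d_il10_dt, jak1 = d_jak1_dt, stat3 = d_stat3_dt,
         mapk = d_mapk_dt, nrf2 = d_nrf2_dt, keap1 = d_keap1_dt,
         sod = d_sod_dt, cat = d_cat_dt, gpx = d_gpx_dt, gsh = d_gsh_dt,
         ros = d_ros_dt, mda = d_mda_dt, hif1a = d_hif1a_dt,
         foxo1_cyt = d_foxo1_dt, irs = d_irs_dt, pirs = d_pirs_dt,
         akt = d_akt_dt, pakt = d_pakt_dt, pi3k = d_pi3k_dt,
         mtor = d_mtor_dt, ampk = d_ampk_dt, crh = d_crh_dt,
         acth = d_acth_dt, cortisol = d_cortisol_dt, renin = d_renin_dt,
         ang2 = d_ang2_dt, aldosterone = d_aldo_dt, insulin = d_insulin_dt,
         glucagon = d_glucagon_dt, glucose = d_glucose_dt)
  })
}
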