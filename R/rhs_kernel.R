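# Fast evaluation kernel mirroring rhs_raw(): list-accessor parameters and
# positional state (parameters as a hashed environment), used by the
# integrator and steady-state solver. Any
# change to the kinetics must be applied to both rhs_raw() and this kernel
# (test-network_model cross-checks them on random states).

.SP <- local({
  i <- seq_along(c("lps", "nfkb", "tnfa", "il6", "il10", "jak1", "stat3",
                   "mapk", "nrf2", "keap1", "sod", "cat", "gpx", "gsh",
                   "ros", "mda", "hif1a", "foxo1_cyt", "irs", "pirs",
                   "akt", "pakt", "pi3k", "mtor", "ampk", "crh", "acth",
                   "cortisol", "renin", "ang2", "aldosterone", "insulin",
                   "glucagon", "glucose"))
  names(i) <- c("lps", "nfkb", "tnfa", "il6", "il10", "jak1", "stat3",
                "mapk", "nrf2", "keap1", "sod", "cat", "gpx", "gsh",
                "ros", "mda", "hif1a", "foxo1_cyt", "irs", "pirs",
                "akt", "pakt", "pi3k", "mtor", "ampk", "crh", "acth",
                "cortisol", "renin", "ang2", "aldosterone", "insulin",
                "glucagon", "glucose")
  i
})

rhs_kernel <- function(y, th) {
  h2 <- function(x, K) { x2 <- (x / K)^2; x2 / (1 + x2) }
  h1 <- function(x, K) x / (K + x)
  lps <- y[1L]; nfkb <- y[2L]; tnfa <- y[3L]; il6 <- y[4L]; il10 <- y[5L]
  jak1 <- y[6L]; stat3 <- y[7L]; mapk <- y[8L]; nrf2 <- y[9L]
  keap1 <- y[10L]; sod <- y[11L]; cat_ <- y[12L]; gpx <- y[13L]
  gsh <- y[14L]; ros <- y[15L]; mda <- y[16L]; hif1a <- y[17L]
  foxo1 <- y[18L]; irs <- y[19L]; pirs <- y[20L]; akt <- y[21L]
  pakt <- y[22L]; pi3k <- y[23L]; mtor <- y[24L]; ampk <- y[25L]
  crh <- y[26L]; acth <- y[27L]; cortisol <- y[28L]; renin <- y[29L]
  ang2 <- y[30L]; aldo <- y[31L]; insulin <- y[32L]; glucagon <- y[33L]
  glucose <- y[34L]

  out <- numeric(34L)
  out[1L] <- th$b_lps + th$v_lps * h2(foxo1, th$K_lps_f) * th$m_lps -
    th$d_lps * lps
  out[2L] <- th$b_nfkb + th$v_nfkb * th$g_inf * h2(lps, th$K_nfkb_l) *
    (1 / (1 + il10 / th$K_nfkb_10)) * th$m_nfkb - th$d_nfkb * nfkb
  out[3L] <- th$b_tnfa + th$v_tnfa *
    {xn <- (nfkb / th$K_tnfa_n)^th$n_tnfa; xn / (1 + xn)} * th$m_tnfa -
    th$d_tnfa * tnfa
  out[4L] <- th$b_il6 + th$v_il6 * h2(nfkb, th$K_il6_n) *
    (1 + th$c_il6_t * h1(tnfa, th$K_il6_t)) *
    (1 + th$c_il6_m * h1(mapk, th$K_il6_m)) * th$m_il6 - th$d_il6 * il6
  out[5L] <- th$b_il10 + th$v_il10 * h2(stat3, th$K_il10_s) * th$m_il10 -
    th$d_il10 * il10
  out[6L] <- th$b_jak1 + th$v_jak1 * h2(il6, th$K_jak1_6) - th$d_jak1 * jak1
  out[7L] <- th$b_stat3 + th$v_stat3 * h2(jak1, th$K_stat3_j) -
    th$d_stat3 * stat3
  out[8L] <- th$b_mapk + th$v_mapk * h2(lps, th$K_mapk_l) - th$d_mapk * mapk
  out[9L] <- th$b_nrf2 * th$m_nrf2 -
    (th$d_nrf2 + th$k_keap * th$g_keap * keap1 * th$m_keap1) * nrf2
  out[10L] <- th$b_keap1 - th$d_keap1 * keap1
  out[11L] <- (th$b_sod + th$v_sod * h2(nrf2, th$K_sod_n)) * th$m_sod /
    th$g_aox - th$d_sod * sod
  out[12L] <- (th$b_cat + th$v_cat * h2(nrf2, th$K_cat_n)) * th$m_cat /
    th$g_aox - th$d_cat * cat_
  out[13L] <- (th$b_gpx + th$v_gpx * h2(nrf2, th$K_gpx_n)) * th$m_gpx /
    th$g_aox - th$d_gpx * gpx
  out[14L] <- th$b_gsh * th$m_gsh / th$g_aox - th$d_gsh * gsh -
    th$k_gshros * ros * gsh
  out[15L] <- (th$b_ros + th$v_ros * th$g_rosgen *
                 (1 + th$c_ros_n * h2(nfkb, th$K_ros_n))) * th$m_ros -
    (th$d_ros + th$k_sodros * sod + th$k_catros * cat_ +
       th$k_gpxros * gpx + th$k_gshc * gsh + th$k_ampkros * ampk) * ros
  out[16L] <- th$b_mda + th$k_mda * ros - th$d_mda * mda
  out[17L] <- th$b_hif + th$v_hif * h2(ros, th$K_hif_r) - th$d_hif * hif1a
  out[18L] <- th$b_fox + th$v_fox * th$g_ins * h2(pakt, th$K_fox_a) *
    th$m_foxo1 - th$d_fox * foxo1
  irs_phos <- th$kp_irs * th$g_ins *
    (1 + th$c_irs_m * h2(mapk, th$K_irs_m)) * irs
  dpirs <- irs_phos - th$kd_irs * pirs
  out[19L] <- -dpirs
  out[20L] <- dpirs
  akt_phos <- th$kp_akt * th$g_ins * h2(pi3k, th$K_akt_p) * akt * th$m_pakt
  dpakt <- akt_phos - th$kd_akt * pakt
  out[21L] <- -dpakt
  out[22L] <- dpakt
  out[23L] <- th$b_pi3k + th$v_pi3k * h1(insulin, th$K_pi3k_i) -
    th$d_pi3k * pi3k
  out[24L] <- th$b_mtor + th$v_mtor * h1(pakt, th$K_mtor_a) - th$d_mtor * mtor
  out[25L] <- th$b_ampk * (1 / (1 + mtor / th$K_ampk_m)) * th$m_ampk -
    th$d_ampk * ampk
  out[26L] <- th$b_crh + th$v_crh * h2(hif1a, th$K_crh_h) *
    (1 + th$c_crh_6 * h1(il6, th$K_crh_6)) * th$m_crh - th$d_crh * crh
  out[27L] <- th$b_acth + th$v_acth * h2(crh, th$K_acth_c) * th$m_acth -
    th$d_acth * acth
  out[28L] <- th$b_cort + th$v_cort *
    {xn <- (acth / th$K_cort_a)^th$n_cort; xn / (1 + xn)} * th$m_cortisol -
    th$d_cort * cortisol
  out[29L] <- th$b_renin + th$v_renin *
    {xn <- (tnfa / th$K_renin_t)^3; xn / (1 + xn)} * th$m_renin -
    th$d_renin * renin
  out[30L] <- th$b_ang2 + th$v_ang2 * h2(renin, th$K_ang2_r) * th$m_ang2 -
    th$d_ang2 * ang2
  out[31L] <- th$b_aldo + th$v_aldo * h2(ang2, th$K_aldo_a) *
    th$m_aldosterone - th$d_aldo * aldo
  out[32L] <- th$b_insulin - th$d_insulin * insulin
  out[33L] <- th$b_glucagon - th$d_glucagon * glucagon
  out[34L] <- th$b_glucose + th$k_glc_g * glucagon -
    (th$d_glucose + th$k_glc_i * insulin) * glucose
  out
}
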