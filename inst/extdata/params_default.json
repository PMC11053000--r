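{
  "format": "stressnet-model",
  "version": 1,
  "species": ["lps", "nfkb", "tnfa", "il6", "il10", "jak1", "stat3", "mapk", "nrf2", "keap1", "sod", "cat", "gpx", "gsh", "ros", "mda", "hif1a", "foxo1_cyt", "irs", "pirs", "akt", "pakt", "pi3k", "mtor", "ampk", "crh", "acth", "cortisol", "renin", "ang2", "aldosterone", "insulin", "glucagon", "glucose"],
  "edges": [
    {
      "from": "lps",
      "to": "nfkb",
      "sign": "activate"
    },
    {
      "from": "nfkb",
      "to": "tnfa",
      "sign": "activate"
    },
    {
      "from": "nfkb",
      "to": "il6",
      "sign": "activate"
    },
    {
      "from": "tnfa",
      "to": "il6",
      "sign": "activate"
    },
    {
      "from": "il6",
      "to": "crh",
      "sign": "activate"
    },
    {
      "from": "ros",
      "to": "hif1a",
      "sign": "activate"
    },
    {
      "from": "hif1a",
      "to": "crh",
      "sign": "activate"
    },
    {
      "from": "crh",
      "to": "acth",
      "sign": "activate"
    },
    {
      "from": "acth",
      "to": "cortisol",
      "sign": "activate"
    },
    {
      "from": "nrf2",
      "to": "sod",
      "sign": "activate"
    },
    {
      "from": "keap1",
      "to": "nrf2",
      "sign": "inhibit"
    },
    {
      "from": "sod",
      "to": "ros",
      "sign": "inhibit"
    },
    {
      "from": "gsh",
      "to": "ros",
      "sign": "inhibit"
    },
    {
      "from": "ros",
      "to": "mda",
      "sign": "activate"
    },
    {
      "from": "pakt",
      "to": "foxo1_cyt",
      "sign": "activate"
    },
    {
      "from": "foxo1_cyt",
      "to": "lps",
      "sign": "activate"
    },
    {
      "from": "il10",
      "to": "nfkb",
      "sign": "inhibit"
    },
    {
      "from": "stat3",
      "to": "il10",
      "sign": "activate"
    },
    {
      "from": "tnfa",
      "to": "renin",
      "sign": "activate"
    },
    {
      "from": "ang2",
      "to": "aldosterone",
      "sign": "activate"
    },
    {
      "from": "aldosterone",
      "to": "sbp",
      "sign": "activate"
    },
    {
      "from": "insulin",
      "to": "pi3k",
      "sign": "activate"
    },
    {
      "from": "pi3k",
      "to": "pakt",
      "sign": "activate"
    },
    {
      "from": "mapk",
      "to": "pirs",
      "sign": "activate"
    },
    {
      "from": "lps",
      "to": "mapk",
      "sign": "activate"
    },
    {
      "from": "mapk",
      "to": "il6",
      "sign": "activate"
    },
    {
      "from": "il6",
      "to": "jak1",
      "sign": "activate"
    },
    {
      "from": "jak1",
      "to": "stat3",
      "sign": "activate"
    },
    {
      "from": "nrf2",
      "to": "cat",
      "sign": "activate"
    },
    {
      "from": "nrf2",
      "to": "gpx",
      "sign": "activate"
    },
    {
      "from": "ros",
      "to": "gsh",
      "sign": "inhibit"
    },
    {
      "from": "cat",
      "to": "ros",
      "sign": "inhibit"
    },
    {
      "from": "gpx",
      "to": "ros",
      "sign": "inhibit"
    },
    {
      "from": "nfkb",
      "to": "ros",
      "sign": "activate"
    },
    {
      "from": "pakt",
      "to": "mtor",
      "sign": "activate"
    },
    {
      "from": "mtor",
      "to": "ampk",
      "sign": "inhibit"
    },
    {
      "from": "ampk",
      "to": "ros",
      "sign": "inhibit"
    },
    {
      "from": "renin",
      "to": "ang2",
      "sign": "activate"
    },
    {
      "from": "glucagon",
      "to": "glucose",
      "sign": "activate"
    },
    {
      "from": "insulin",
      "to": "glucose",
      "sign": "inhibit"
    }
  ],
  "totals": {
    "irs": 1,
    "akt": 1
  },
  "parameters": {
    "kp_akt": 1.71428571428571,
    "kd_akt": 2,
    "kp_irs": 0.208504801097394,
    "kd_irs": 2,
    "c_irs_m": 4.54358552631579,
    "b_fox": 1.4372574385511,
    "v_fox": 2.1259163432514,
    "b_lps": 0.476190476190476,
    "v_lps": 11.047619047619,
    "b_mapk": 1.78125,
    "v_mapk": 6.09375,
    "b_jak1": 2,
    "v_jak1": 5,
    "b_stat3": 0.777777777777778,
    "v_stat3": 7.22222222222222,
    "b_il10": 0.385714285714286,
    "v_il10": 8.49642857142857,
    "b_nfkb": 1.83970792767733,
    "v_nfkb": 5.86519297635605,
    "b_tnfa": 0.000102401045437938,
    "v_tnfa": 0.0273789415821519,
    "n_tnfa": 6,
    "b_il6": 2.48601104920621,
    "v_il6": 9.10148975581767,
    "c_il6_t": 0.8,
    "c_il6_m": 0.5,
    "b_nrf2": 1.6,
    "d_nrf2": 1,
    "k_keap": 0.6,
    "b_keap1": 2,
    "d_keap1": 2,
    "b_sod": 0.657738095238095,
    "v_sod": 0.561309523809524,
    "b_cat": 0.821428571428572,
    "v_cat": 0.292857142857143,
    "b_gpx": 0.821428571428572,
    "v_gpx": 0.292857142857143,
    "b_gsh": 2.42055835521456,
    "d_gsh": 2,
    "k_gshros": 0.420558355214558,
    "b_mtor": 0.542857142857144,
    "v_mtor": 3.88571428571428,
    "b_ampk": 4,
    "d_ampk": 2,
    "b_ros": 2.88260951615037,
    "v_ros": 0.287819941876062,
    "d_ros": 0.4,
    "c_ros_n": 0.6,
    "k_sodros": 1.2,
    "k_catros": 0.4,
    "k_gpxros": 0.4,
    "k_gshc": 0.6,
    "k_ampkros": 0.2,
    "b_mda": 0.302000930665426,
    "k_mda": 0.697999069334574,
    "d_mda": 1,
    "b_hif": 1.14883654310143,
    "v_hif": 14.2558172844929,
    "b_crh": 1.41034897713598,
    "v_crh": 7.30414391064211,
    "c_crh_6": 1.7,
    "b_acth": 0.34,
    "v_acth": 26.535,
    "b_cort": 24.0283498476944,
    "v_cort": 2360.54977515231,
    "n_cort": 4,
    "b_renin": 1.99200799200799,
    "v_renin": 6.01250590131131,
    "b_ang2": 1.77777777777778,
    "v_ang2": 22.2222222222222,
    "b_aldo": 0.607407407407408,
    "v_aldo": 13.9259259259259,
    "b_pi3k": 1,
    "v_pi3k": 2,
    "b_insulin": 1,
    "d_insulin": 1,
    "b_glucagon": 1,
    "d_glucagon": 1,
    "b_glucose": 2,
    "k_glc_g": 0.5,
    "k_glc_i": 0.5,
    "d_glucose": 2,
    "d_lps": 2,
    "d_nfkb": 4,
    "d_tnfa": 12,
    "d_il6": 4,
    "d_il10": 3,
    "d_jak1": 3,
    "d_stat3": 3,
    "d_mapk": 3,
    "d_sod": 1,
    "d_cat": 1,
    "d_gpx": 1,
    "d_mda.1": 1,
    "d_hif": 4,
    "d_fox": 2,
    "d_pi3k": 2,
    "d_mtor": 2,
    "d_crh": 4,
    "d_acth": 4,
    "d_cort": 3,
    "d_renin": 2,
    "d_ang2": 4,
    "d_aldo": 2,
    "K_lps_f": 2.5,
    "K_nfkb_l": 0.9,
    "K_nfkb_10": 2,
    "K_tnfa_n": 2.35,
    "K_il6_n": 2.5,
    "K_il6_t": 0.0005,
    "K_il6_m": 2,
    "K_il10_s": 1.5,
    "K_jak1_6": 2,
    "K_stat3_j": 1.5,
    "K_mapk_l": 2,
    "K_sod_n": 0.8,
    "K_cat_n": 0.8,
    "K_gpx_n": 0.8,
    "K_ros_n": 2.2,
    "K_hif_r": 2,
    "K_fox_a": 0.5,
    "K_irs_m": 1.5,
    "K_akt_p": 1,
    "K_pi3k_i": 1,
    "K_mtor_a": 0.5,
    "K_ampk_m": 1,
    "K_crh_h": 2,
    "K_crh_6": 1.2,
    "K_acth_c": 2.5,
    "K_cort_a": 6.5,
    "K_renin_t": 0.0002,
    "K_ang2_r": 3,
    "K_aldo_a": 3,
    "g_inf": 1,
    "g_keap": 1,
    "g_aox": 1,
    "g_rosgen": 1,
    "g_ins": 1,
    "m_lps": 1,
    "m_nfkb": 1,
    "m_tnfa": 1,
    "m_il6": 1,
    "m_il10": 1,
    "m_nrf2": 1,
    "m_keap1": 1,
    "m_sod": 1,
    "m_cat": 1,
    "m_gpx": 1,
    "m_gsh": 1,
    "m_ros": 1,
    "m_foxo1": 1,
    "m_pakt": 1,
    "m_ampk": 1,
    "m_crh": 1,
    "m_acth": 1,
    "m_cortisol": 1,
    "m_renin": 1,
    "m_ang2": 1,
    "m_aldosterone": 1,
    "stress_alpha_inf": 4,
    "stress_beta_keap": 4,
    "stress_beta_aox": 1.2,
    "stress_beta_ros": 2,
    "stress_gamma_ins": 2
  }
}
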