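{
  "name": "CB-PB synthetic default",
  "comment": "SYNTHETIC stand-in configuration: inter-compartment rates are not published values; they were calibrated once so that the analytic observables reproduce the printed operating point (unquenched amplitude-weighted lifetime 1.66 ns; one OCP at k_Q = 540/ns -> ~0.21 ns and ~11% brightness; two OCPs -> ~0.09 ns and ~6%). See the methods vignette.",
  "compartments": [
    {
      "id": "a",
      "class": "APC660",
      "extinction": 0.007,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "b",
      "class": "APC660",
      "extinction": 0.02,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "c",
      "class": "APC660",
      "extinction": 0.02,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "d",
      "class": "APC660",
      "extinction": 0.007,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "e",
      "class": "APC660",
      "extinction": 0.02,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "f",
      "class": "APC660",
      "extinction": 0.02,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "a'",
      "class": "APC680",
      "extinction": 0.003,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "d'",
      "class": "APC680",
      "extinction": 0.003,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "CPC-a",
      "class": "CPC650",
      "extinction": 0.15,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "CPC-b",
      "class": "CPC650",
      "extinction": 0.15,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "CPC-c",
      "class": "CPC650",
      "extinction": 0.15,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "CPC-d",
      "class": "CPC650",
      "extinction": 0.15,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "CPC-e",
      "class": "CPC650",
      "extinction": 0.15,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    },
    {
      "id": "CPC-f",
      "class": "CPC650",
      "extinction": 0.15,
      "decay_ns1": 0.602409638554217,
      "radiative_fraction": 0.5
    }
  ],
  "rates": [
    {
      "from": "a",
      "to": "b",
      "k_ns1": 27.16
    },
    {
      "from": "b",
      "to": "a",
      "k_ns1": 27.16
    },
    {
      "from": "c",
      "to": "d",
      "k_ns1": 27.16
    },
    {
      "from": "d",
      "to": "c",
      "k_ns1": 27.16
    },
    {
      "from": "e",
      "to": "f",
      "k_ns1": 27.16
    },
    {
      "from": "f",
      "to": "e",
      "k_ns1": 27.16
    },
    {
      "from": "a",
      "to": "c",
      "k_ns1": 27.16
    },
    {
      "from": "c",
      "to": "a",
      "k_ns1": 27.16
    },
    {
      "from": "b",
      "to": "d",
      "k_ns1": 27.16
    },
    {
      "from": "d",
      "to": "b",
      "k_ns1": 27.16
    },
    {
      "from": "e",
      "to": "b",
      "k_ns1": 27.16
    },
    {
      "from": "b",
      "to": "e",
      "k_ns1": 27.16
    },
    {
      "from": "e",
      "to": "d",
      "k_ns1": 27.16
    },
    {
      "from": "d",
      "to": "e",
      "k_ns1": 27.16
    },
    {
      "from": "f",
      "to": "a",
      "k_ns1": 27.16
    },
    {
      "from": "a",
      "to": "f",
      "k_ns1": 27.16
    },
    {
      "from": "f",
      "to": "c",
      "k_ns1": 27.16
    },
    {
      "from": "c",
      "to": "f",
      "k_ns1": 27.16
    },
    {
      "from": "a",
      "to": "a'",
      "k_ns1": 265.1
    },
    {
      "from": "a'",
      "to": "a",
      "k_ns1": 66.275
    },
    {
      "from": "d",
      "to": "d'",
      "k_ns1": 265.1
    },
    {
      "from": "d'",
      "to": "d",
      "k_ns1": 66.275
    },
    {
      "from": "CPC-a",
      "to": "a",
      "k_ns1": 13.46
    },
    {
      "from": "a",
      "to": "CPC-a",
      "k_ns1": 4.038
    },
    {
      "from": "CPC-b",
      "to": "b",
      "k_ns1": 13.46
    },
    {
      "from": "b",
      "to": "CPC-b",
      "k_ns1": 4.038
    },
    {
      "from": "CPC-c",
      "to": "c",
      "k_ns1": 13.46
    },
    {
      "from": "c",
      "to": "CPC-c",
      "k_ns1": 4.038
    },
    {
      "from": "CPC-d",
      "to": "d",
      "k_ns1": 13.46
    },
    {
      "from": "d",
      "to": "CPC-d",
      "k_ns1": 4.038
    },
    {
      "from": "CPC-e",
      "to": "e",
      "k_ns1": 13.46
    },
    {
      "from": "e",
      "to": "CPC-e",
      "k_ns1": 4.038
    },
    {
      "from": "CPC-f",
      "to": "f",
      "k_ns1": 13.46
    },
    {
      "from": "f",
      "to": "CPC-f",
      "k_ns1": 4.038
    }
  ],
  "quench_sites": [
    "a",
    "b",
    "c",
    "d",
    "e",
    "f",
    "a'",
    "d'"
  ],
  "spectra": {
    "CPC650": {
      "peak_nm": 650,
      "fwhm_nm": 26
    },
    "APC660": {
      "peak_nm": 660,
      "fwhm_nm": 28
    },
    "APC680": {
      "peak_nm": 680,
      "fwhm_nm": 26
    }
  }
}
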