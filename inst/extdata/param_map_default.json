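{
  "components": {
    "puff_rate": {
      "ip3": {
        "form": "hill",
        "fit": {
          "vmax": 0.0976518347134933,
          "K": 0.0657384580248337,
          "h": 1.83441011899822,
          "offset": 0,
          "rss": 5.08393300733718e-06
        },
        "x": [0.05, 0.1, 0.3, 1, 3, 8],
        "y": [0.0367222620211955, 0.066856038584316, 0.0921441895739195, 0.0951225871129793, 0.0981078980108949, 0.0987473655475908],
        "status": "ok"
      },
      "nch": {
        "form": "linear",
        "fit": {
          "intercept": -0.0014190417110854,
          "slope": 0.0194716379569363,
          "rss": 1.46916929064865e-06
        },
        "x": [2, 3, 5, 7, 10],
        "y": [0.0380055677595982, 0.0568596238447108, 0.0959141169669886, 0.133958499082016, 0.193901208628541],
        "status": "ok"
      }
    },
    "open_shape": {
      "ip3": {
        "form": "hill",
        "fit": {
          "vmax": 1.68384058872248,
          "K": 1e-09,
          "h": 0.148739830015128,
          "offset": 1,
          "rss": 2.08765289533517
        },
        "x": [0.05, 0.1, 0.3, 1, 3, 8],
        "y": [3.43992890442172, 3.38543915877853, 2.69800258978744, 2.17543152764555, 2.07676883887292, 2.19071597104488],
        "status": "ok"
      },
      "nch": {
        "form": "hill",
        "fit": {
          "vmax": 1.17768045436677,
          "K": 1e-09,
          "h": 0.596004115570065,
          "offset": 1,
          "rss": 0.0404570326731675
        },
        "x": [2, 3, 5, 7, 10],
        "y": [2.20792398275064, 2.30079953411367, 2.24488247421461, 2.13934585093784, 2.04204212816162],
        "status": "ok"
      }
    },
    "open_rate": {
      "ip3": {
        "form": "hill",
        "fit": {
          "vmax": 48.9400887283552,
          "K": 0.0769949063862732,
          "h": 1.6066001494052,
          "offset": 0,
          "rss": 1.23802814271478
        },
        "x": [0.05, 0.1, 0.3, 1, 3, 8],
        "y": [16.4202100699398, 29.3304832523099, 44.3317746173337, 47.8061025810307, 48.1821902751723, 49.659051011366],
        "status": "ok"
      },
      "nch": {
        "form": "linear",
        "fit": {
          "intercept": 19.9388936032672,
          "slope": 5.16010821970784,
          "rss": 22.7642140275261
        },
        "x": [2, 3, 5, 7, 10],
        "y": [27.3392647473538, 36.1771965578189, 48.5138677838004, 57.4532341027773, 69.5338267566973],
        "status": "ok"
      }
    }
  },
  "reference": {
    "ip3": 1,
    "ca_base": 0.01,
    "ca_open": 0.6,
    "n_ch": 5,
    "lambda_cl": 50
  },
  "ref_values": {
    "puff_rate": 0.0951225871129793,
    "open_shape": 2.17543152764555,
    "open_rate": 47.8061025810307
  },
  "ranges": {
    "ip3": [0.05, 8],
    "nch": [2, 10]
  },
  "n_samples": 10000,
  "seed": 20121227,
  "partial": false
}
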