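# Docking scores against phosphodiesterase 3B (PDE3B); more negative =
# better. Reference drug: olprinone.
ligand_id,target_id,moldock,rerank,interaction_energy,steric,hbond,is_reference
4a,PDE3B,-108.136,-32.3135,-125.473,-118.475,-6.99816,FALSE
4b,PDE3B,-111.562,-78.3614,-120.628,-116.517,-4.11087,FALSE
4c,PDE3B,-119.362,-89.9521,-128.679,-124.015,-4.66410,FALSE
4d,PDE3B,-116.080,-79.6175,-125.506,-120.981,-4.52482,FALSE
4e,PDE3B,-111.031,-77.0171,-120.362,-116.213,-4.14992,FALSE
4f,PDE3B,-118.320,-83.1092,-128.576,-119.230,-9.34526,FALSE
4g,PDE3B,-130.663,-98.3234,-141.452,-132.962,-8.49026,FALSE
4h,PDE3B,-109.303,-73.0475,-118.408,-114.611,-3.79774,FALSE
4i,PDE3B,-115.557,-85.9591,-123.242,-119.762,-3.48020,FALSE
4j,PDE3B,-118.900,-87.8734,-126.795,-120.784,-6.01043,FALSE
4k,PDE3B,-128.312,-81.8875,-132.019,-122.726,-9.29270,FALSE
4l,PDE3B,-116.616,-65.0245,-127.611,-118.031,-9.58031,FALSE
4m,PDE3B,-115.537,-85.9622,-123.216,-119.743,-3.47298,FALSE
4n,PDE3B,-126.841,-94.7604,-130.499,-122.702,-7.79698,FALSE
4o,PDE3B,-125.361,-94.0195,-131.192,-126.334,-8.55344,FALSE
olprinone,PDE3B,-105.404,-82.9526,-116.144,-112.107,-4.03755,TRUE
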