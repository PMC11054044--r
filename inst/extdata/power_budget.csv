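component,time_ratio,current_ma,consumption_masec
2x BME680,1,1.8,1.8
DC-DC converter,1,0.06,0.06
MCU low-power mode,0.9995,2.1e-3,2.1e-3
MCU BLE 2dBm,1.6e-4,17.2,2.75e-3
MCU I2C transmittance,3.36e-4,1,3.36e-4
FET leakage,1,0.001,0.001
MCU ADC measurement,1.10e-8,2,2.2e-8
V divider + ADC meas. curr.,1.10e-8,2.25,2.47e-8
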